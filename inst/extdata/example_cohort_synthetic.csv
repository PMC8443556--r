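patient_id,t,PTA_VS_0.25,PTA_VS_0.5,PTA_VS_1,PTA_VS_2,PTA_VS_3,PTA_VS_4,PTA_VS_6,PTA_VS_8,PTA_H_0.25,PTA_H_0.5,PTA_H_1,PTA_H_2,PTA_H_3,PTA_H_4,PTA_H_6,PTA_H_8,SRT,SDS,MDL,MDR,Size,Koos,decision
P001,0,8.55,9.47,14.81,25.68,25.45,42.09,54.61,66.39,7.35,5.12,15.61,19.54,12.72,17.44,18.96,29.87,9.94,100,39.96,98.2,7.93,1,WaS
P001,296,8.91,18.47,21.23,24.34,36.07,36.49,44.07,56.07,9.52,1.42,6.35,21.75,12.01,11.77,25.9,22.65,22.65,89.56,51.04,80.87,8.93,1,WaS
P001,648,16.67,16.8,17.87,27.86,33.4,40.37,55.51,55.85,1.07,6.2,9.36,9.87,-3.31,11.44,23.33,27.26,11.62,100,22.5,98.38,9.62,1,WaS
P001,1016,20.05,16.22,26.31,25.36,43.94,49.69,50.63,61.66,0.06,4.21,-10,19.26,14.89,16.95,23.28,22.85,21.93,92.74,45.65,86.03,10.85,1,WaS
P001,1370,11.56,9.02,25.84,37.18,35.56,47.33,52.55,66.33,5.64,15.96,10.17,-2.14,16.96,16.46,22.52,25.2,21.78,100,46.53,99.04,11.94,1,WaS
P001,1694,12.69,28.68,18.47,33.27,42.07,48.38,59.4,62.09,12.07,6.19,8.45,10.99,21.23,20.3,23.63,34.98,34.21,89.12,56.83,84.24,12.99,1,WaS
P001,2115,27.64,17.1,20.49,40.66,43.56,44.11,57.51,68.4,8.67,1.63,9.24,5.65,16.51,22.19,30.64,22.46,21.09,86.05,,85.74,14.18,1,WaS
P001,2439,19.26,15.71,36.5,31.19,30.54,41.51,64.03,69.5,5.65,6.59,11.72,3.46,15.27,18.56,18.67,23.35,25.28,99.37,43.61,91.07,14.92,1,WaS
P002,0,15.8,12.87,15.93,34.57,40.87,50.82,47.68,74.83,12.06,9.77,8.92,21.96,13.49,13.16,26.51,27.82,23.04,97.69,34.54,97.46,10.71,2,WaS
P002,342,23.41,21.19,26.84,28.47,32.84,48.57,52.33,69.27,7.25,4.52,12,13.99,17.44,18.69,21.57,36.11,16.24,94.87,41.55,94.08,11.18,2,WaS
P002,707,28.81,20.15,23.63,37.55,37.23,50.41,66.69,77.17,,,,,,,,,,87.38,54.71,85.22,11.61,3,Active
P003,0,22.7,28.26,31.66,49.1,56.74,62.91,62.5,78.87,23.08,21.21,22.74,25.38,25.69,32.98,33.36,43.55,33.08,82.65,46.63,76.96,6.12,1,WaS
P003,351,26.3,40.12,39.82,55.11,51.55,62.16,74.97,84.82,23.85,21.64,30.64,24.45,26.26,34.63,41.67,46.13,39.8,75.58,71.21,73.89,11.64,1,WaS
P003,829,34.68,41.24,48.14,55.52,60.31,64.69,79.59,88.93,23.01,23.62,20.42,25.44,31.74,34.18,41.77,37.96,56.27,72.78,89.59,65.42,19.64,1,WaS
P003,1110,38.79,47.9,44.65,56.7,69.07,77.26,80.12,92.66,28.97,26.71,22.3,36.27,37.64,36.75,38.93,37.77,52.46,61.37,,59.91,23.93,1,WaS
P003,1313,48.02,46.57,55.48,56.5,66.47,71.08,75.86,88.11,21.89,30.77,28.99,32.97,28.37,31.53,43.21,43,41.02,,,51.99,27.16,1,Active
P004,0,13.99,17.1,23.22,23.97,34.24,46.35,53.47,66.02,7.52,14.93,10.76,12.71,17.68,21.26,24.67,40.59,14.14,94.89,37.72,93.76,8.95,1,WaS
P004,235,16.47,29.16,26.64,47.89,34.09,52.14,68.56,69.57,8.04,8.33,2.96,15.48,20.14,10.33,24.43,24.78,38.04,85.09,64.61,75.46,9.33,1,WaS
P004,550,16.1,19.48,26.34,43.06,45.27,40.82,58.01,71.47,18.15,17.73,12.62,23.09,11.61,25.7,23.02,32.55,,86.88,44.3,79.69,10.61,2,Active
P005,0,17.95,23.13,20.84,27.69,41.84,37.34,58.05,62.03,0.45,13.41,14.92,16.31,11.19,25.37,22.4,27.86,26.12,91.31,,84.68,4.98,3,WaS
P005,293,20.23,13.03,31.89,36.02,30.26,42.31,68.1,71.69,,,,,,,,,19.7,97.65,38.52,91.17,10.42,3,WaS
P005,664,12.95,26.19,19.3,28.56,43.09,52.83,55.96,73.57,12.77,4.21,9.07,17.62,11.79,26.07,14.66,26.93,26.5,88.74,55.58,86.79,17.42,3,Active
P006,0,4.71,20.14,15.27,18.24,23.5,44.05,63.94,64.19,-0.86,1.51,9.86,5.53,18.07,11.09,21.86,27.81,20.21,100,41.32,97.75,11.43,1,WaS
P006,303,21.8,23.34,17.87,35.91,37.91,47.18,61.15,69.88,,,,,,,,,28.58,97.36,56.15,93.35,10.34,1,WaS
P006,559,15.81,23.92,19.49,37.1,36.78,51.21,60.79,67.6,-2.57,13.42,7.04,15.4,18.22,22.46,19.98,36.1,25.68,87.04,46.12,84.18,9.45,2,WaS
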