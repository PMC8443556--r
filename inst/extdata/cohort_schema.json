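{
  "description": "Canonical cohort CSV dialect: one row per checkup, comma-separated, UTF-8, header row, '.' decimal separator, missing cells empty or N/A. Audiometric values at or above the audiometer ceiling (default 110 dB) are real measurements, flagged on read, not missing.",
  "mandatory": ["patient_id", "t", "decision"],
  "columns": {
    "patient_id": "opaque patient identifier (string)",
    "t": "days since the patient's first checkup (>= 0; use months_to_days() to convert)",
    "PTA_VS_0.25": "diseased-ear pure-tone threshold at 0.25 kHz, dB HL",
    "PTA_VS_0.5": "diseased-ear threshold at 0.5 kHz, dB HL",
    "PTA_VS_1": "diseased-ear threshold at 1 kHz, dB HL",
    "PTA_VS_2": "diseased-ear threshold at 2 kHz, dB HL",
    "PTA_VS_3": "diseased-ear threshold at 3 kHz, dB HL",
    "PTA_VS_4": "diseased-ear threshold at 4 kHz, dB HL",
    "PTA_VS_6": "diseased-ear threshold at 6 kHz, dB HL",
    "PTA_VS_8": "diseased-ear threshold at 8 kHz, dB HL",
    "PTA_H_0.25": "healthy-ear threshold at 0.25 kHz, dB HL",
    "PTA_H_0.5": "healthy-ear threshold at 0.5 kHz, dB HL",
    "PTA_H_1": "healthy-ear threshold at 1 kHz, dB HL",
    "PTA_H_2": "healthy-ear threshold at 2 kHz, dB HL",
    "PTA_H_3": "healthy-ear threshold at 3 kHz, dB HL",
    "PTA_H_4": "healthy-ear threshold at 4 kHz, dB HL",
    "PTA_H_6": "healthy-ear threshold at 6 kHz, dB HL",
    "PTA_H_8": "healthy-ear threshold at 8 kHz, dB HL",
    "SRT": "speech reception threshold, dB (diseased ear)",
    "SDS": "speech discrimination score, percent",
    "MDL": "maximum discrimination level, dB",
    "MDR": "maximum discrimination ratio, percent",
    "Size": "maximal 1D tumor size on T2 MRI, mm",
    "Koos": "Koos grade, 1-4",
    "decision": "treatment decision at this checkup: WaS or Active"
  },
  "ranges": {
    "dB_columns": [-10, 130],
    "percent_columns": [0, 100],
    "Koos": [1, 4]
  }
}
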