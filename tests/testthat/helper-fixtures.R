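# Shared fixtures, all built in code.

FREQ_LABELS <- c("0.25", "0.5", "1", "2", "3", "4", "6", "8")

make_audiogram <- function(values) setNames(values, FREQ_LABELS)

# One fully-populated checkup row in canonical column order.
checkup_row <- function(patient_id, t, decision = "WaS",
                        vs = rep(40, 8), h = rep(20, 8),
                        SRT = 45, SDS = 80, MDL = 70, MDR = 75,
                        Size = 10, Koos = 2) {
  row <- data.frame(patient_id = patient_id, t = t, stringsAsFactors = FALSE)
  for (k in seq_along(FREQ_LABELS)) row[[paste0("PTA_VS_", FREQ_LABELS[k])]] <- vs[k]
  for (k in seq_along(FREQ_LABELS)) row[[paste0("PTA_H_", FREQ_LABELS[k])]] <- h[k]
  row$SRT <- SRT; row$SDS <- SDS; row$MDL <- MDL; row$MDR <- MDR
  row$Size <- Size; row$Koos <- Koos; row$decision <- decision
  row
}

tiny_cohort <- function() {
  as_cohort(rbind(
    checkup_row("A", 0), checkup_row("A", 400), checkup_row("A", 800),
    checkup_row("B", 0, Size = 12, Koos = 3),
    checkup_row("B", 350, Size = 13, Koos = 3, decision = "Active")
  ))
}

# The eight published worked inference examples for the static tree:
# feature vector, full node path and prediction.
table4_records <- function() {
  list(
    list(f = list(Koos = 1, SRT = 57, PTA_VS_SR8 = 11.3, PTA_H_SR8 = 1.3, PTA_D_AR4 = 28.8),
         path = c(1, 3, 6, 9, 11, 12), pred = "No"),
    list(f = list(Koos = 1, SRT = 30, PTA_VS_SR8 = 4.7, PTA_H_SR8 = 0.2, PTA_D_AR4 = 5.0),
         path = c(1, 3, 6, 8), pred = "Yes"),
    list(f = list(Koos = 2, SRT = 110, PTA_VS_SR8 = 10.7, PTA_H_SR8 = 7.6, PTA_D_AR4 = 43.8),
         path = c(1, 3, 7), pred = "No"),
    list(f = list(Koos = 2, SRT = 37, PTA_VS_SR8 = 2.1, PTA_H_SR8 = 0.1, PTA_D_AR4 = 16.3),
         path = c(1, 2, 5), pred = "Yes"),
    list(f = list(Koos = 3, SRT = 60, PTA_VS_SR8 = 4.6, PTA_H_SR8 = 9.8, PTA_D_AR4 = 17.5),
         path = c(1, 3, 7), pred = "No"),
    list(f = list(Koos = 3, SRT = 110, PTA_VS_SR8 = 2.1, PTA_H_SR8 = 3.3, PTA_D_AR4 = 26.3),
         path = c(1, 2, 5), pred = "Yes"),
    list(f = list(Koos = 4, SRT = 110, PTA_VS_SR8 = 5.2, PTA_H_SR8 = 2.3, PTA_D_AR4 = 68.8),
         path = c(1, 3, 6, 9, 10), pred = "No"),
    list(f = list(Koos = 4, SRT = 110, PTA_VS_SR8 = 0, PTA_H_SR8 = 3.0, PTA_D_AR4 = 98.8),
         path = c(1, 2, 5), pred = "Yes")
  )
}

# Closed-form ordinary least squares via the normal equations, used as
# an independent oracle for the fitted slopes/intercepts.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
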