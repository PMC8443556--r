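# Derived audiometric and temporal features.
#
# Row-based metrics (static track): each checkup's audiogram is reduced
# to its average (AR), fitted slope (SR) and intercept (IR) over a
# frequency range -- basic (0.25-4 kHz) or full (0.25-8 kHz) -- for each
# ear, plus the inter-ear difference of averages (D_AR).
#
# Column-based metrics (dynamic track): a variable observed over a
# patient's checkups is reduced to its time average (AC), least-squares
# slope vs time (SC, units per day), intercept at t = 0 (IC), last
# difference (LD, last minus previous checkup) and total difference
# (TD, last minus first).

range_freqs <- function(range_id) {
  switch(range_id,
         basic = PTA_BASIC,
         full  = PTA_FREQS,
         stop("unknown range_id '", range_id, "' (use 'basic' or 'full')"))
}

check_audiogram <- function(audiogram) {
  want <- vapply(PTA_FREQS, freq_label, "")
  if (is.null(names(audiogram)) || !setequal(names(audiogram), want)) {
    stop("audiogram must be a named vector with frequency keys exactly {",
         paste(want, collapse = ", "), "} kHz")
  }
  audiogram[want] # canonical order: result independent of input order
}

#' Average pure-tone threshold over a frequency range
#'
#' Arithmetic mean of the audiogram over the basic (0.25--4 kHz,
#' inclusive) or full (0.25--8 kHz) range. Missing any in-range
#' threshold makes the result missing -- no partial averaging.
#'
#' @param audiogram named numeric vector, names the 8 frequencies in kHz
#'   (`"0.25"`, `"0.5"`, `"1"`, `"2"`, `"3"`, `"4"`, `"6"`, `"8"`),
#'   values in dB HL; `NA` for unmeasured.
#' @param range_id `"basic"` or `"full"`.
#' @return mean threshold in dB, or `NA`.
#' @export
#' @examples
#' ag <- setNames(c(10, 10, 20, 20, 30, 30, 40, 50),
#'                c("0.25", "0.5", "1", "2", "3", "4", "6", "8"))
#' pta_average(ag, "basic") # 20
pta_average <- function(audiogram, range_id) {
  audiogram <- check_audiogram(audiogram)
  f <- range_freqs(range_id)
  v <- audiogram[vapply(f, freq_label, "")]
  if (anyNA(v)) return(NA_real_)
  mean(v)
}

#' Linear fit of an audiogram over a frequency range
#'
#' Ordinary least-squares fit of threshold (dB) against frequency over
#' the chosen range. The abscissa is frequency in kHz by default; the
#' alternatives (`"log2khz"`: log2 of kHz, i.e. octaves re 1 kHz;
#' `"index"`: 1, 2, ... position in the range) change the slope units.
#'
#' @inheritParams pta_average
#' @param abscissa regressor scale, one of `"khz"`, `"log2khz"`, `"index"`.
#' @return named numeric `c(slope, intercept)` (dB per abscissa unit and
#'   dB), or both `NA` if any in-range threshold is missing.
#' @export
pta_linfit <- function(audiogram, range_id,
                       abscissa = c("khz", "log2khz", "index")) {
  abscissa <- match.arg(abscissa)
  audiogram <- check_audiogram(audiogram)
  f <- range_freqs(range_id)
  y <- as.numeric(audiogram[vapply(f, freq_label, "")])
  if (anyNA(y)) return(c(slope = NA_real_, intercept = NA_real_))
  x <- switch(abscissa, khz = f, log2khz = log2(f), index = seq_along(f))
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  c(slope = b, intercept = a)
}

#' Names of the static (per-checkup) feature vector
#'
#' The 16 raw thresholds, speech audiometry, tumor size and Koos grade,
#' plus the derived AR/SR/IR metrics per ear and range and the inter-ear
#' average differences.
#'
#' @return character vector of feature names (target excluded).
#' @export
cbr_feature_names <- function() {
  derived <- as.vector(outer(
    c("PTA_VS", "PTA_H"),
    as.vector(outer(c("AR", "SR", "IR"), c(4, 8), paste0)),
    paste, sep = "_"))
  c(pta_cols("VS"), pta_cols("H"), "SRT", "SDS", "MDL", "MDR", "Size", "Koos",
    derived, "PTA_D_AR4", "PTA_D_AR8")
}

row_audiogram <- function(row, ear) {
  setNames(as.numeric(row[1, pta_cols(ear)]), vapply(PTA_FREQS, freq_label, ""))
}

derive_row_metrics <- function(cohort, abscissa = "khz") {
  n <- nrow(cohort)
  out <- list()
  for (ear in c("VS", "H")) {
    ags <- as.matrix(cohort[, pta_cols(ear)])
    colnames(ags) <- vapply(PTA_FREQS, freq_label, "")
    for (rid in c("basic", "full")) {
      suf <- if (rid == "basic") "4" else "8"
      ar <- apply(ags, 1, pta_average, range_id = rid)
      fit <- t(apply(ags, 1, pta_linfit, range_id = rid, abscissa = abscissa))
      out[[paste0("PTA_", ear, "_AR", suf)]] <- ar
      out[[paste0("PTA_", ear, "_SR", suf)]] <- fit[, "slope"]
      out[[paste0("PTA_", ear, "_IR", suf)]] <- fit[, "intercept"]
    }
  }
  out[["PTA_D_AR4"]] <- out[["PTA_VS_AR4"]] - out[["PTA_H_AR4"]]
  out[["PTA_D_AR8"]] <- out[["PTA_VS_AR8"]] - out[["PTA_H_AR8"]]
  as.data.frame(out)
}

#' Build the static (case-based) analysis data set
#'
#' One feature vector per checkup; patient identity and time are
#' deliberately dropped so every record is an independent, anonymized
#' sample. The target is that checkup's decision (`Active` mapped to
#' `Yes`, `WaS` to `No`).
#'
#' @param cohort a `vs_cohort`, typically already passed through
#'   [clean_complete()] for the fields required downstream.
#' @param abscissa regressor scale for the slope/intercept fits, see
#'   [pta_linfit()].
#' @return data.frame with [cbr_feature_names()] columns and a `target`
#'   factor with levels `No`, `Yes`.
#' @export
build_cbr_dataset <- function(cohort, abscissa = "khz") {
  stopifnot(inherits(cohort, "vs_cohort"))
  if (nrow(cohort) == 0) {
    out <- as.data.frame(setNames(
      rep(list(numeric(0)), length(cbr_feature_names())), cbr_feature_names()))
    out$target <- factor(character(0), levels = c("No", "Yes"))
    return(out)
  }
  raw <- as.data.frame(cohort)[, c(pta_cols("VS"), pta_cols("H"),
                                   "SRT", "SDS", "MDL", "MDR", "Size", "Koos")]
  out <- cbind(raw, derive_row_metrics(cohort, abscissa = abscissa))
  out <- out[, cbr_feature_names()]
  out$target <- factor(ifelse(cohort$decision == "Active", "Yes", "No"),
                       levels = c("No", "Yes"))
  rownames(out) <- NULL
  out
}

#' Temporal summary of one variable over a patient's checkups
#'
#' @param t checkup times in days, strictly increasing.
#' @param values variable values at those times; pairs with a missing
#'   value are dropped before summarizing.
#' @return named numeric vector with elements
#'   \describe{
#'     \item{AC}{time average (plain mean of the observed values).}
#'     \item{SC}{ordinary least-squares slope vs `t`, units per day.}
#'     \item{IC}{fit intercept at `t = 0`.}
#'     \item{LD}{last difference: last minus second-to-last value.}
#'     \item{TD}{total difference: last minus first value.}
#'   }
#'   For a single observed point, `SC` and `LD` are `NA`, `AC = IC =`
#'   the value and `TD = 0`.
#' @export
#' @examples
#' column_summary(c(0, 100, 200), c(10, 11, 12))
column_summary <- function(t, values) {
  if (length(t) != length(values)) stop("t and values must have equal length")
  keep <- !is.na(values) & !is.na(t)
  t <- t[keep]; v <- values[keep]
  if (length(t) == 0) stop("column_summary: empty series")
  if (is.unsorted(t, strictly = TRUE)) stop("column_summary: t must be strictly increasing")
  n <- length(t)
  if (n == 1) {
    return(c(AC = v, SC = NA_real_, IC = v, LD = NA_real_, TD = 0))
  }
  b <- stats::cov(t, v) / stats::var(t)
  a <- mean(v) - b * mean(t)
  c(AC = mean(v), SC = b, IC = a, LD = v[n] - v[n - 1], TD = v[n] - v[1])
}

#' Default base variables for the dynamic (per-patient) data set
#' @return character vector of base variable names.
#' @export
pda_base_variables <- function() {
  c("Koos", "Size", "SRT", "PTA_VS_AR4", "PTA_VS_AR8", "PTA_D_AR4", "PTA_D_AR8")
}

#' Build the dynamic (personalized) analysis data set
#'
#' One feature vector per patient: each base variable observed over the
#' patient's checkups is summarized by [column_summary()] into `_AC`,
#' `_SC`, `_IC`, `_LD` and `_TD` features (e.g. `Size_SC`, `Koos_LD`).
#' Every checkup of the record belongs to the wait-and-scan phase (the
#' decision is the label of the final one), so all checkups enter the
#' summaries. The target is `Yes` if the history ends in an `Active`
#' decision, else `No`.
#'
#' @param cohort a `vs_cohort`.
#' @param base_variables raw or derived per-checkup variables to
#'   summarize; defaults to [pda_base_variables()].
#' @param abscissa see [pta_linfit()] (used for the derived row metrics).
#' @return data.frame with `patient_id`, the summary features and a
#'   `target` factor with levels `No`, `Yes`. Patients with a single
#'   checkup get `NA` slope-type features and trigger a warning.
#' @export
build_pda_dataset <- function(cohort, base_variables = pda_base_variables(),
                              abscissa = "khz") {
  stopifnot(inherits(cohort, "vs_cohort"))
  feats <- as.vector(t(outer(base_variables, c("AC", "SC", "IC", "LD", "TD"),
                             paste, sep = "_")))
  if (nrow(cohort) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(feats)), feats))
    out <- cbind(patient_id = character(0), out)
    out$target <- factor(character(0), levels = c("No", "Yes"))
    return(out)
  }
  per_checkup <- cbind(as.data.frame(cohort), derive_row_metrics(cohort, abscissa))
  unknown <- setdiff(base_variables, names(per_checkup))
  if (length(unknown)) stop("unknown base variable(s): ", paste(unknown, collapse = ", "))
  hs <- split(per_checkup, per_checkup$patient_id)
  rows <- lapply(hs, function(h) {
    vec <- setNames(rep(NA_real_, length(feats)), feats)
    for (bv in base_variables) {
      ok <- !is.na(h[[bv]])
      if (!any(ok)) next
      cs <- column_summary(h$t[ok], h[[bv]][ok])
      vec[paste(bv, names(cs), sep = "_")] <- cs
    }
    vec
  })
  singletons <- names(hs)[vapply(hs, nrow, 0L) == 1]
  if (length(singletons)) {
    warning("build_pda_dataset: ", length(singletons),
            " patient(s) with a single checkup; slope and last-difference ",
            "features are missing for them")
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(patient_id = names(hs), out)
  oc <- patient_outcomes(cohort)
  out$target <- factor(ifelse(oc$outcome[match(out$patient_id, oc$patient_id)] == "Active",
                              "Yes", "No"), levels = c("No", "Yes"))
  rownames(out) <- NULL
  out
}
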