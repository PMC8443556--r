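# Cohort data model: one row per diagnostic checkup.
#
# A `vs_cohort` is a data.frame with canonical columns (see
# `cohort_columns()`), sorted by patient and checkup time. Audiometric
# cells can be in one of three states: present, missing (NA), or at the
# audiometer ceiling -- a real measurement ("could not be measured below
# 110 dB"), stored as the ceiling value and flagged in the "ceiling"
# attribute. Ceiling cells are NOT missing and survive complete-record
# cleaning.

#' Canonical cohort column names
#'
#' One row per checkup: patient id, time since the patient's first
#' checkup in days, pure-tone thresholds (dB HL) for the diseased (`VS`)
#' and healthy (`H`) ears at 0.25--8 kHz, speech audiometry (SRT dB,
#' SDS %, MDL dB, MDR %), maximal 1D tumor size (mm), Koos grade (1--4)
#' and the treatment decision label (`"WaS"` or `"Active"`).
#'
#' @return character vector of column names.
#' @export
cohort_columns <- function() {
  c("patient_id", "t",
    pta_cols("VS"), pta_cols("H"),
    "SRT", "SDS", "MDL", "MDR", "Size", "Koos", "decision")
}

# columns subject to the audiometer ceiling (dB-valued, bounded above)
ceiling_columns <- function() c(pta_cols("VS"), pta_cols("H"), "SRT", "MDL")

numeric_cohort_columns <- function() {
  setdiff(cohort_columns(), c("patient_id", "decision"))
}

#' Construct a cohort from a checkup-level data frame
#'
#' Sorts rows by patient and time, validates invariants and attaches the
#' ceiling-flag matrix (cells at or above `audiometric_ceiling` in
#' dB-valued columns are flagged as ceiling measurements).
#'
#' @param x data.frame containing at least `patient_id`, `t` and
#'   `decision`; other canonical columns are added as `NA` if absent.
#' @param audiometric_ceiling audiometer limit in dB; values at or above
#'   it are flagged (not treated as missing). Default 110.
#' @param provenance free-text source tag stored as an attribute.
#' @return a `vs_cohort` data.frame.
#' @export
as_cohort <- function(x, audiometric_ceiling = 110, provenance = "unspecified") {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  mandatory <- c("patient_id", "t", "decision")
  miss <- setdiff(mandatory, names(x))
  if (length(miss)) {
    stop("cohort schema error: missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in setdiff(cohort_columns(), names(x))) x[[col]] <- NA_real_
  x <- x[, cohort_columns()]
  x$patient_id <- as.character(x$patient_id)
  x$decision <- as.character(x$decision)
  for (col in numeric_cohort_columns()) x[[col]] <- as.numeric(x[[col]])
  x <- x[order(x$patient_id, x$t), , drop = FALSE]
  rownames(x) <- NULL

  cc <- ceiling_columns()
  flags <- !is.na(as.matrix(x[, cc])) & as.matrix(x[, cc]) >= audiometric_ceiling
  attr(x, "ceiling") <- flags
  attr(x, "audiometric_ceiling") <- audiometric_ceiling
  attr(x, "provenance") <- provenance
  class(x) <- c("vs_cohort", "data.frame")
  validate_cohort(x)
  x
}

#' Validate cohort invariants
#'
#' Checks value ranges (thresholds, SRT, MDL in \[-10, 130\] dB; SDS, MDR
#' in \[0, 100\] %; Koos in 1..4; size and time non-negative), uniqueness
#' of (patient_id, t), and that at most one checkup per patient is
#' labeled `Active` and, if present, it is the last one.
#'
#' @param x a `vs_cohort`.
#' @return `x` invisibly; errors on violation.
#' @export
validate_cohort <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  key <- paste(x$patient_id, x$t)
  if (anyDuplicated(key)) {
    stop("cohort integrity error: duplicate (patient_id, t) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  chk_range <- function(cols, lo, hi, what) {
    v <- unlist(x[, cols], use.names = FALSE)
    bad <- !is.na(v) & (v < lo | v > hi)
    if (any(bad)) stop("cohort range error: ", what, " outside [", lo, ", ", hi, "]")
  }
  chk_range(c(pta_cols("VS"), pta_cols("H"), "SRT", "MDL"), -10, 130, "dB value")
  chk_range(c("SDS", "MDR"), 0, 100, "percentage")
  if (any(!is.na(x$Koos) & !x$Koos %in% 1:4)) stop("cohort range error: Koos must be in 1..4")
  if (any(!is.na(x$Size) & x$Size < 0)) stop("cohort range error: Size must be >= 0")
  if (any(is.na(x$t) | x$t < 0)) stop("cohort range error: t must be present and >= 0")
  bad_dec <- !is.na(x$decision) & !x$decision %in% c("WaS", "Active")
  if (any(bad_dec)) stop("cohort range error: decision must be 'WaS' or 'Active'")
  for (h in split(seq_len(nrow(x)), x$patient_id)) {
    dec <- x$decision[h]
    act <- which(!is.na(dec) & dec == "Active")
    if (length(act) > 1 || (length(act) == 1 && act != length(h))) {
      stop("cohort integrity error: patient ", x$patient_id[h[1]],
           " must have at most one Active decision, at the last checkup")
    }
  }
  invisible(x)
}

#' Read a cohort from CSV
#'
#' Expects one row per checkup, a header row, comma separation, `.` as
#' decimal separator and missing cells encoded as empty or `"N/A"`.
#' Unparseable numeric cells become missing and are counted in the
#' cleaning log (attribute `"parse_log"`, also reported via `message()`).
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping canonical column
#'   names to file column names, e.g. `c(patient_id = "id")`; unmapped
#'   canonical names are looked up verbatim.
#' @param audiometric_ceiling see [as_cohort()].
#' @return a `vs_cohort`.
#' @export
read_cohort <- function(path, schema = NULL, audiometric_ceiling = 110) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("", "NA", "N/A", "n/a"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) next
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  mandatory <- c("patient_id", "t", "decision")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss)) {
    stop("cohort schema error: CSV lacks mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  n_bad <- 0L
  for (col in intersect(numeric_cohort_columns(), names(raw))) {
    v <- raw[[col]]
    if (is.numeric(v)) next
    num <- suppressWarnings(as.numeric(v))
    n_bad <- n_bad + sum(is.na(num) & !is.na(v))
    raw[[col]] <- num
  }
  if (n_bad > 0) message("read_cohort: ", n_bad, " unparseable numeric cell(s) set to missing")
  out <- as_cohort(raw, audiometric_ceiling = audiometric_ceiling, provenance = path)
  attr(out, "parse_log") <- list(unparseable_cells = n_bad)
  out
}

#' Write a cohort to CSV
#'
#' Canonical dialect: comma-separated, UTF-8, header row, `.` decimal
#' separator, missing cells empty. Full double precision is kept so that
#' [read_cohort()] round-trips all present values exactly.
#'
#' @param cohort a `vs_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (col in numeric_cohort_columns()) {
    df[[col]] <- vapply(df[[col]], function(v) {
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, "")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Keep only complete records
#'
#' Drops checkups missing any of the `required` fields. Ceiling-flagged
#' measurements are present values and are never dropped. No imputation
#' is ever performed; surviving values are untouched (the operation is
#' idempotent). Removal counts are reported via `message()` and stored
#' in the `"cleaning"` attribute (a JSON-ready list).
#'
#' @param cohort a `vs_cohort`.
#' @param required character vector of canonical column names that must
#'   be present; empty vector keeps everything.
#' @return the filtered `vs_cohort`. If nothing survives, an empty
#'   cohort is returned with a warning of class `"vsdss_empty_cohort"`.
#' @export
clean_complete <- function(cohort, required) {
  stopifnot(inherits(cohort, "vs_cohort"))
  required <- intersect(unique(required), cohort_columns())
  if (length(required) == 0 || nrow(cohort) == 0) {
    attr(cohort, "cleaning") <- list(required = required, removed = 0L,
                                     retained = nrow(cohort))
    return(cohort)
  }
  keep <- rep(TRUE, nrow(cohort))
  for (col in required) keep <- keep & !is.na(cohort[[col]])
  removed <- sum(!keep)
  out <- cohort[keep, , drop = FALSE]
  attr(out, "ceiling") <- attr(cohort, "ceiling")[keep, , drop = FALSE]
  attr(out, "audiometric_ceiling") <- attr(cohort, "audiometric_ceiling")
  attr(out, "provenance") <- attr(cohort, "provenance")
  class(out) <- class(cohort)
  rownames(out) <- NULL
  attr(out, "cleaning") <- list(required = required, removed = removed,
                                retained = nrow(out))
  message("clean_complete: removed ", removed, " of ", nrow(cohort),
          " checkup record(s); ", nrow(out), " retained")
  if (nrow(out) == 0) {
    warning(warningCondition("clean_complete: no complete records remain",
                             class = "vsdss_empty_cohort"))
  }
  out
}

#' Ceiling flags of a cohort
#'
#' @param cohort a `vs_cohort`.
#' @return logical matrix (rows = checkups, columns = dB-valued fields)
#'   marking measurements at the audiometer ceiling.
#' @export
ceiling_flags <- function(cohort) attr(cohort, "ceiling")

#' Split a cohort into per-patient histories
#'
#' @param cohort a `vs_cohort`.
#' @return named list of per-patient data.frames, checkups in time order.
#' @export
patient_histories <- function(cohort) {
  split(as.data.frame(cohort), cohort$patient_id)
}

#' Patient-level outcomes
#'
#' A patient's outcome is `Active` if any checkup decision is `Active`
#' (by the cohort invariants this can only be the last one), else `WaS`.
#'
#' @param cohort a `vs_cohort`.
#' @return data.frame with columns `patient_id`, `outcome`, `n_checkups`.
#' @export
patient_outcomes <- function(cohort) {
  hs <- patient_histories(cohort)
  data.frame(
    patient_id = names(hs),
    outcome = vapply(hs, function(h) {
      if (any(!is.na(h$decision) & h$decision == "Active")) "Active" else "WaS"
    }, ""),
    n_checkups = vapply(hs, nrow, 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Convert days to months and back
#'
#' Checkup time is stored in days since the patient's first checkup;
#' clinical summaries are often quoted in months. One month is taken as
#' 365.25/12 days.
#'
#' @param d days; @param m months.
#' @return converted numeric vector.
#' @export
days_to_months <- function(d) d / (365.25 / 12)

#' @rdname days_to_months
#' @export
months_to_days <- function(m) m * (365.25 / 12)

#' @export
print.vs_cohort <- function(x, ...) {
  po <- patient_outcomes(x)
  cat("<vs_cohort> ", nrow(x), " checkups, ", nrow(po), " patients (",
      sum(po$outcome == "Active"), " Active, ", sum(po$outcome == "WaS"),
      " WaS)\n", sep = "")
  cat("provenance:", attr(x, "provenance"), "\n")
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... (", nrow(x) - 6, " more rows)\n", sep = "")
  invisible(x)
}
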