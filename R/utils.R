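# Small shared helpers.

#' Round half away from zero
#'
#' Decimal rounding with ties going up (0.05 -> 0.1), unlike [round()]'s
#' round-half-even. Used when displaying average ranks at one decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(3.25, 1) # 3.3
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code under a fixed RNG seed without disturbing the caller's RNG
# state; NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# The eight audiometric frequencies in kHz, shared across modules.
PTA_FREQS <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
PTA_BASIC <- c(0.25, 0.5, 1, 2, 3, 4)

freq_label <- function(f) {
  # "0.25", "0.5", "1", ... without trailing zeros
  sub("0+$", "", sub("\\.$", "", format(f, trim = TRUE, scientific = FALSE)))
}

pta_cols <- function(ear = c("VS", "H")) {
  ear <- match.arg(ear)
  paste0("PTA_", ear, "_", vapply(PTA_FREQS, freq_label, ""))
}

# Map a two-class label vector (factor/character/logical/0-1) onto 0/1
# with Active/Yes/1/TRUE as the positive class.
as_binary01 <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) stop("numeric labels must be 0/1")
    return(as.integer(x))
  }
  pos <- c("Active", "Yes", "yes", "1", "TRUE")
  neg <- c("WaS", "No", "no", "0", "FALSE")
  out <- ifelse(x %in% pos, 1L, ifelse(x %in% neg, 0L, NA_integer_))
  if (anyNA(out) && !anyNA(x)) {
    stop("unrecognized class labels: ",
         paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

# Largest-remainder apportionment of n items into parts with the given
# weights; deterministic, ties broken by part order.
largest_remainder <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}
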