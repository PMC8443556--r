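# Classification performance metrics.
#
# Positive class = active treatment ("Active"/"Yes"/1). Any metric with
# an undefined denominator (e.g. TNR with no real negatives) is NA, not
# zero.

#' Confusion counts from labels and predictions
#'
#' @param labels true binary labels (`Active`/`WaS`, `Yes`/`No`,
#'   logical, or 0/1).
#' @param predictions predicted labels, same encodings.
#' @return a `vs_confusion` list with `TP`, `TN`, `FP`, `FN`, `P`
#'   (= TP + FN) and `N` (= TN + FP).
#' @export
confusion <- function(labels, predictions) {
  y <- as_binary01(labels)
  p <- as_binary01(predictions)
  if (length(y) != length(p)) stop("labels and predictions must have equal length")
  if (length(y) == 0) stop("confusion: empty input")
  out <- list(TP = sum(y == 1 & p == 1), TN = sum(y == 0 & p == 0),
              FP = sum(y == 0 & p == 1), FN = sum(y == 1 & p == 0))
  out$P <- out$TP + out$FN
  out$N <- out$TN + out$FP
  structure(out, class = "vs_confusion")
}

#' @export
print.vs_confusion <- function(x, ...) {
  cat("<vs_confusion> TP=", x$TP, " TN=", x$TN, " FP=", x$FP, " FN=", x$FN,
      " (P=", x$P, ", N=", x$N, ")\n", sep = "")
  invisible(x)
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney U statistic normalized by `P * N`
#' (probability that a random positive scores above a random negative,
#' ties counted one half) -- identical to the trapezoidal integral of
#' the ROC curve.
#'
#' @param scores continuous classifier outputs, larger = more positive.
#' @param labels true binary labels.
#' @return AUC in \[0, 1\], or `NA` when a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary01(labels)
  if (length(scores) != length(y)) stop("scores and labels must have equal length")
  P <- sum(y == 1); N <- sum(y == 0)
  if (P == 0 || N == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Average square error
#'
#' Mean squared difference between the 0/1 target and the continuous
#' output of the discrimination function.
#'
#' @param targets true binary labels.
#' @param outputs continuous outputs in any range (typically \[0, 1\]).
#' @return non-negative scalar.
#' @export
ase <- function(targets, outputs) {
  y <- as_binary01(targets)
  if (length(outputs) != length(y)) stop("targets and outputs must have equal length")
  mean((y - outputs)^2)
}

#' Classification metrics report
#'
#' Applies the standard confusion-matrix formulas: ACC = (TP+TN)/(P+N),
#' TPR = TP/P, TNR = TN/N, PPV = TP/(TP+FP); with `scores` and `labels`
#' also AUC ([roc_auc()]) and ASE ([ase()]). Undefined denominators
#' yield `NA`.
#'
#' @param counts a `vs_confusion` from [confusion()].
#' @param scores optional continuous outputs for AUC/ASE.
#' @param labels labels matching `scores` (required with `scores`).
#' @return a `vs_metrics` list with `acc`, `tpr`, `tnr`, `ppv`, `auc`,
#'   `ase`.
#' @export
classification_metrics <- function(counts, scores = NULL, labels = NULL) {
  stopifnot(inherits(counts, "vs_confusion"))
  out <- list(
    acc = safe_div(counts$TP + counts$TN, counts$P + counts$N),
    tpr = safe_div(counts$TP, counts$P),
    tnr = safe_div(counts$TN, counts$N),
    ppv = safe_div(counts$TP, counts$TP + counts$FP),
    auc = NA_real_, ase = NA_real_
  )
  if (!is.null(scores)) {
    if (is.null(labels)) stop("labels are required alongside scores")
    out$auc <- roc_auc(scores, labels)
    out$ase <- ase(labels, scores)
  }
  structure(out, class = "vs_metrics")
}

#' @export
print.vs_metrics <- function(x, ...) {
  v <- unlist(x)
  cat("<vs_metrics> ",
      paste(toupper(names(v)), formatC(v, digits = 3, format = "fg"),
            sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Balanced train/validation/test split
#'
#' The majority class is first down-sampled (seeded, without
#' replacement) to the minority count, then each class is partitioned
#' into train/validation/test by the given proportions using
#' largest-remainder rounding per class, so the partitions are disjoint,
#' their union is the balanced set and class ratios match within
#' rounding.
#'
#' @param dataset data.frame with a two-level target column.
#' @param proportions three percentages summing to 100 (default
#'   `c(train = 50, valid = 30, test = 20)`).
#' @param seed integer seed.
#' @param target_col name of the target column.
#' @return list with elements `train`, `valid`, `test` (data.frames).
#' @export
balanced_split <- function(dataset, proportions = c(train = 50, valid = 30, test = 20),
                           seed = 1, target_col = "target") {
  stopifnot(target_col %in% names(dataset))
  if (length(proportions) != 3 || abs(sum(proportions) - 100) > 1e-9) {
    stop("proportions must be three percentages summing to 100")
  }
  y <- as_binary01(dataset[[target_col]])
  idx_by_class <- split(seq_len(nrow(dataset)), y)
  if (length(idx_by_class) < 2) stop("balanced_split: need both classes present")
  n_min <- min(lengths(idx_by_class))
  if (n_min < 5) {
    stop("balanced_split: smallest class has ", n_min,
         " member(s); at least 5 are required")
  }
  with_seed(seed, {
    parts <- list(train = integer(0), valid = integer(0), test = integer(0))
    for (cls in names(idx_by_class)) {
      idx <- idx_by_class[[cls]]
      idx <- sample(idx, n_min) # down-sample majority; permutes both classes
      sizes <- largest_remainder(n_min, proportions)
      cut1 <- seq_len(sizes[1])
      cut2 <- seq_len(sizes[2]) + sizes[1]
      cut3 <- seq_len(sizes[3]) + sizes[1] + sizes[2]
      parts$train <- c(parts$train, idx[cut1])
      parts$valid <- c(parts$valid, idx[cut2])
      parts$test  <- c(parts$test,  idx[cut3])
    }
    lapply(parts, function(i) {
      out <- dataset[sort(i), , drop = FALSE]
      rownames(out) <- NULL
      out
    })
  })
}
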