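# Ensemble-consensus feature selection.
#
# Several supervised rankers each nominate their ten most important
# variables; a variable enters the candidate set when it occurs in at
# least `min_occurrence` of the top-10 lists OR its average rank over
# the lists containing it is at most `max_avg_rank`. The final minimal
# set is an expert decision and is therefore modeled as an explicit
# override, not an algorithm.

#' Construct a ranked top-10 feature list
#'
#' @param method_id name of the ranking method.
#' @param variables variable names, most important first; duplicates are
#'   an error.
#' @param ranks integer ranks of the entries (default their positions).
#'   Explicit ranks allow gaps when a published listing skips a slot.
#' @return a `vs_ranked_list`.
#' @export
ranked_list <- function(method_id, variables, ranks = seq_along(variables)) {
  variables <- as.character(variables)
  if (anyDuplicated(variables)) {
    stop("ranked_list: duplicate variable(s) in '", method_id, "': ",
         paste(unique(variables[duplicated(variables)]), collapse = ", "))
  }
  if (length(ranks) != length(variables) || anyDuplicated(ranks)) {
    stop("ranked_list: ranks must be unique and match variables in length")
  }
  if (length(variables) > 10 || any(ranks < 1) || any(ranks > 10)) {
    stop("ranked_list: at most 10 entries with ranks in 1..10")
  }
  structure(list(method_id = method_id, variables = variables,
                 ranks = as.integer(ranks)),
            class = "vs_ranked_list")
}

#' @export
print.vs_ranked_list <- function(x, ...) {
  cat("<vs_ranked_list> ", x$method_id, "\n", sep = "")
  print(setNames(x$variables, x$ranks))
  invisible(x)
}

#' Rank features by a supervised importance method
#'
#' Fits one of five established learners to a complete numeric feature
#' matrix with a binary target and returns its top-10 variables by
#' importance. The contract is the ranking itself, not the learner
#' internals; scoring delegates to \pkg{rpart} (tree importance),
#' \pkg{randomForest} (mean Gini decrease), \pkg{xgboost} (gain),
#' per-variable logistic-regression deviance reduction, and
#' \pkg{glmnet} (order of entry along the lasso path). Ties -- including
#' variables the learner never uses, which score zero -- are broken by
#' dataset column order, and results are deterministic given `seed`.
#'
#' @param dataset data.frame of numeric features plus a two-level
#'   `target` column (levels `No`/`Yes` or equivalent).
#' @param method_id one of `"decision_tree"`, `"random_forest"`,
#'   `"gradient_boosting"`, `"logistic_regression"`, `"lasso"`.
#' @param seed integer seed.
#' @param target_col name of the target column.
#' @param n_top list length (default 10; shorter with a warning when
#'   fewer variables exist).
#' @return a `vs_ranked_list`.
#' @export
rank_features <- function(dataset,
                          method_id = c("decision_tree", "random_forest",
                                        "gradient_boosting",
                                        "logistic_regression", "lasso"),
                          seed = 1, target_col = "target", n_top = 10) {
  method_id <- match.arg(method_id)
  stopifnot(target_col %in% names(dataset))
  y <- as_binary01(dataset[[target_col]])
  x <- dataset[, setdiff(names(dataset), c(target_col, "patient_id")), drop = FALSE]
  if (!all(vapply(x, is.numeric, TRUE))) stop("features must be numeric")
  if (anyNA(x) || anyNA(y)) stop("rank_features requires a complete matrix")
  if (length(unique(y)) < 2) stop("constant target: nothing to rank against")
  vars <- names(x)
  if (length(vars) < n_top) {
    warning("rank_features: only ", length(vars), " variables available")
    n_top <- length(vars)
  }
  xm <- as.matrix(x)

  score <- with_seed(seed, switch(
    method_id,
    decision_tree = {
      fit <- rpart::rpart(
        factor(y) ~ ., data = cbind(x, y = y),
        method = "class",
        control = rpart::rpart.control(minsplit = 4, cp = 0, xval = 0))
      imp <- fit$variable.importance
      setNames(ifelse(vars %in% names(imp), imp[vars], 0), vars)
    },
    random_forest = {
      fit <- randomForest::randomForest(x, factor(y), ntree = 500, importance = FALSE)
      imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
      setNames(imp[vars], vars)
    },
    gradient_boosting = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(xm, label = y, nthread = 1),
        nrounds = 50, verbose = 0)
      imp <- xgboost::xgb.importance(model = fit)
      s <- setNames(rep(0, length(vars)), vars)
      s[imp$Feature] <- imp$Gain
      s
    },
    logistic_regression = {
      # per-variable deviance reduction of a univariate logistic fit;
      # robust to the quasi-separation that breaks joint z statistics
      null_dev <- stats::glm(y ~ 1, family = stats::binomial())$deviance
      vapply(vars, function(v) {
        fit <- suppressWarnings(stats::glm(y ~ x[[v]], family = stats::binomial()))
        null_dev - fit$deviance
      }, 0)
    },
    lasso = {
      fit <- glmnet::glmnet(xm, y, family = "binomial", nlambda = 200)
      entry <- apply(as.matrix(fit$beta) != 0, 1, function(nz) {
        if (any(nz)) which(nz)[1] else Inf
      })
      # earlier entry on the regularization path = more important
      setNames(max(entry[is.finite(entry)], 0) + 1 - entry, vars)
    }))

  ord <- order(-score, seq_along(vars)) # ties by column order
  ranked_list(method_id, vars[ord][seq_len(n_top)])
}

#' Consensus table over ranked feature lists
#'
#' For every variable occurring in any list: `num`, the number of lists
#' containing it, and `avg`, the mean of its ranks over those lists
#' (also shown at one decimal, round-half-up, as `avg_display`). A
#' variable is `selected` when `num >= min_occurrence` or
#' `avg <= max_avg_rank`. Entries are ordered by decreasing `num`, then
#' increasing `avg`, then name; the result does not depend on the order
#' of the input lists.
#'
#' @param lists list of [ranked_list()] objects (at least one).
#' @param min_occurrence occurrence threshold (default 3).
#' @param max_avg_rank average-rank threshold (default 5).
#' @return a `vs_consensus` data.frame with columns `variable`, `num`,
#'   `rank_sum`, `avg`, `avg_display`, `selected`.
#' @export
consensus_table <- function(lists, min_occurrence = 3, max_avg_rank = 5) {
  if (length(lists) == 0) stop("consensus_table: need at least one ranked list")
  stopifnot(all(vapply(lists, inherits, TRUE, "vs_ranked_list")))
  long <- do.call(rbind, lapply(lists, function(l) {
    data.frame(variable = l$variables, rank = l$ranks, stringsAsFactors = FALSE)
  }))
  agg <- lapply(split(long$rank, long$variable), function(r) {
    c(num = length(r), rank_sum = sum(r))
  })
  tab <- data.frame(
    variable = names(agg),
    num = vapply(agg, `[[`, 0, "num"),
    rank_sum = vapply(agg, `[[`, 0, "rank_sum"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$avg <- tab$rank_sum / tab$num
  tab$avg_display <- round_half_up(tab$avg, 1)
  tab$selected <- tab$num >= min_occurrence | tab$avg <= max_avg_rank
  tab <- tab[order(-tab$num, tab$avg, tab$variable), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "min_occurrence") <- min_occurrence
  attr(tab, "max_avg_rank") <- max_avg_rank
  class(tab) <- c("vs_consensus", "data.frame")
  tab
}

#' Candidate variables from a consensus table
#'
#' Returns the rule-selected variables, or -- because the final minimal
#' set is an interactive expert decision the rule cannot reproduce -- an
#' explicit override set when one is given (see [cbr_expert_final()],
#' [pda_expert_final()]).
#'
#' @param table a `vs_consensus` from [consensus_table()].
#' @param override optional character vector of variable names replacing
#'   the rule output.
#' @return character vector of variable names.
#' @export
select_candidates <- function(table, override = NULL) {
  if (!is.null(override)) return(as.character(override))
  table$variable[table$selected]
}

#' @export
print.vs_consensus <- function(x, ...) {
  cat("<vs_consensus> rule: num >= ", attr(x, "min_occurrence"),
      " or avg <= ", attr(x, "max_avg_rank"), "\n", sep = "")
  df <- as.data.frame(x)
  df$avg <- NULL
  print(df)
  invisible(x)
}

#' Export a consensus table as CSV
#'
#' @param table a `vs_consensus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
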