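# Selector-by-classifier benchmarking grid.
#
# Each cell: select features (a ranking method's top-10 or a fixed
# expert set, computed on the learning data), fit one classifier on the
# training partition, report test metrics plus the average of the
# train- and validation-partition metrics. A failing cell is recorded
# as missing and the run continues.

fit_classifier <- function(classifier, train, features, target_col, seed) {
  y <- as_binary01(train[[target_col]])
  x <- train[, features, drop = FALSE]
  with_seed(seed, switch(
    classifier,
    decision_tree = {
      fit <- learn_tree(cbind(x, target = factor(ifelse(y == 1, "Yes", "No"),
                                                 levels = c("No", "Yes"))),
                        criterion = "gini", max_depth = 5, min_leaf = 5)
      function(newdata) predict(fit, newdata[, features, drop = FALSE], type = "prob")
    },
    random_forest = {
      fit <- randomForest::randomForest(x, factor(y), ntree = 500)
      function(newdata) predict(fit, newdata[, features, drop = FALSE],
                                type = "prob")[, "1"]
    },
    gradient_boosting = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 3,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(as.matrix(x), label = y, nthread = 1),
        nrounds = 50, verbose = 0)
      function(newdata) {
        predict(fit, xgboost::xgb.DMatrix(
          as.matrix(newdata[, features, drop = FALSE]), nthread = 1))
      }
    },
    logistic_regression = {
      df <- cbind(x, .y = y)
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      function(newdata) {
        suppressWarnings(as.numeric(predict(fit, newdata[, features, drop = FALSE],
                                            type = "response")))
      }
    },
    svm_rbf = {
      fit <- e1071::svm(x, factor(y), kernel = "radial", probability = TRUE)
      function(newdata) {
        pr <- predict(fit, newdata[, features, drop = FALSE], probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    },
    neural_network = {
      fit <- nnet::nnet(x, y, size = 5, decay = 0.01, maxit = 300,
                        trace = FALSE, entropy = TRUE)
      function(newdata) as.numeric(predict(fit, newdata[, features, drop = FALSE]))
    },
    stop("unknown classifier '", classifier, "'")
  ))
}

partition_metrics <- function(score_fun, data, target_col) {
  scores <- score_fun(data)
  preds <- ifelse(scores >= 0.5, "Yes", "No")
  classification_metrics(confusion(data[[target_col]], preds),
                         scores = scores, labels = data[[target_col]])
}

#' Benchmark feature selectors against classifiers
#'
#' Runs every combination of feature selector and classifier on a fixed
#' balanced train/validation/test split of the data set. Selectors are
#' either ranking methods (see [rank_features()]; the top-10 variables
#' are computed on the pooled train+validation partitions) or fixed
#' variable sets (e.g. the expert sets). Classifiers delegate to
#' established implementations; the harness, the split and the
#' reporting are the contract. The whole run is seeded and
#' reproducible; a classifier failure leaves its cell missing.
#'
#' @param dataset data.frame of numeric features plus a two-level
#'   `target` column.
#' @param selectors named list; each element is a ranking `method_id`
#'   string or a character vector of feature names.
#' @param classifiers subset of `c("decision_tree", "random_forest",
#'   "gradient_boosting", "logistic_regression", "svm_rbf",
#'   "neural_network")`.
#' @param proportions,seed passed to [balanced_split()].
#' @param target_col name of the target column.
#' @return a `vs_benchmark`: list with `acc` (test-accuracy matrix in
#'   percent with `Avg` margins), `cells` (per-cell `vs_metrics` for
#'   the test set), `learn_cells` (averaged train/validation metrics)
#'   and `split` (the partitions used).
#' @export
grid_benchmark <- function(dataset,
                           selectors = list(expert = cbr_expert_final()),
                           classifiers = c("decision_tree", "random_forest",
                                           "gradient_boosting",
                                           "logistic_regression", "svm_rbf",
                                           "neural_network"),
                           proportions = c(train = 50, valid = 30, test = 20),
                           seed = 1, target_col = "target") {
  if (is.null(names(selectors)) || any(names(selectors) == "")) {
    stop("selectors must be a named list")
  }
  split3 <- balanced_split(dataset, proportions, seed = seed, target_col = target_col)
  learn_data <- rbind(split3$train, split3$valid)

  feature_sets <- lapply(selectors, function(sel) {
    if (length(sel) == 1 && sel %in% c("decision_tree", "random_forest",
                                       "gradient_boosting",
                                       "logistic_regression", "lasso")) {
      n_feat <- length(setdiff(names(dataset), c(target_col, "patient_id")))
      rank_features(learn_data, sel, seed = seed, target_col = target_col,
                    n_top = min(10, n_feat))$variables
    } else {
      missing_vars <- setdiff(sel, names(dataset))
      if (length(missing_vars)) {
        stop("selector features not in dataset: ", paste(missing_vars, collapse = ", "))
      }
      as.character(sel)
    }
  })

  empty_metrics <- structure(list(acc = NA_real_, tpr = NA_real_, tnr = NA_real_,
                                  ppv = NA_real_, auc = NA_real_, ase = NA_real_),
                             class = "vs_metrics")
  cells <- list(); learn_cells <- list()
  acc <- matrix(NA_real_, nrow = length(selectors), ncol = length(classifiers),
                dimnames = list(names(selectors), classifiers))
  for (s in names(selectors)) {
    for (cl in classifiers) {
      key <- paste(s, cl, sep = ".")
      res <- tryCatch({
        score_fun <- fit_classifier(cl, split3$train, feature_sets[[s]],
                                    target_col, seed)
        test_m <- partition_metrics(score_fun, split3$test, target_col)
        tr_m <- partition_metrics(score_fun, split3$train, target_col)
        va_m <- partition_metrics(score_fun, split3$valid, target_col)
        avg_m <- structure(as.list((unlist(tr_m) + unlist(va_m)) / 2),
                           class = "vs_metrics")
        list(test = test_m, learn = avg_m)
      }, error = function(e) {
        warning("grid_benchmark: cell ", key, " failed: ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) {
        cells[[key]] <- empty_metrics; learn_cells[[key]] <- empty_metrics
      } else {
        cells[[key]] <- res$test; learn_cells[[key]] <- res$learn
        acc[s, cl] <- res$test$acc * 100
      }
    }
  }
  acc_full <- cbind(acc, Avg = rowMeans(acc, na.rm = TRUE))
  acc_full <- rbind(acc_full, Avg = colMeans(acc_full, na.rm = TRUE))
  structure(list(acc = acc_full, cells = cells, learn_cells = learn_cells,
                 feature_sets = feature_sets, split = split3, seed = seed),
            class = "vs_benchmark")
}

#' @export
print.vs_benchmark <- function(x, ...) {
  cat("<vs_benchmark> test-set accuracy (%), selectors x classifiers\n")
  print(round(x$acc, 1))
  invisible(x)
}

#' Export a benchmark accuracy grid as CSV
#'
#' @param benchmark a `vs_benchmark`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_benchmark_csv <- function(benchmark, path) {
  utils::write.csv(round(benchmark$acc, 1), path, row.names = TRUE)
  invisible(path)
}
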