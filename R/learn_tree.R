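# Greedy top-down induction of a binary decision tree.
#
# At each node every (variable, threshold) candidate -- thresholds are
# midpoints between consecutive distinct observed values -- is scored by
# the split criterion; rows with a missing value are sent with the
# majority branch (the side holding more of the non-missing rows) and
# that side is recorded as the node's `missing_to`, so the learned tree
# routes future missing inputs the same way. Node ids are assigned in
# breadth-first order, matching the tabular layout of the reference
# trees.

split_score <- function(y_true, y_false, criterion) {
  n_t <- length(y_true); n_f <- length(y_false)
  if (n_t == 0 || n_f == 0) return(-Inf)
  if (criterion == "gini") {
    gini <- function(y) {
      p <- mean(y)
      2 * p * (1 - p)
    }
    y_all <- c(y_true, y_false)
    n <- n_t + n_f
    gini(y_all) - (n_t / n) * gini(y_true) - (n_f / n) * gini(y_false)
  } else { # chi_square: Pearson statistic of the 2x2 split-by-class table
    obs <- rbind(c(sum(y_true), n_t - sum(y_true)),
                 c(sum(y_false), n_f - sum(y_false)))
    rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
    if (any(cs == 0)) return(0)
    expd <- outer(rs, cs) / n
    sum((obs - expd)^2 / expd)
  }
}

best_split <- function(x, y, criterion, min_leaf) {
  best <- list(score = -Inf)
  for (v in names(x)) {
    xv <- x[[v]]
    obs <- !is.na(xv)
    u <- sort(unique(xv[obs]))
    if (length(u) < 2) next
    thr <- (u[-1] + u[-length(u)]) / 2
    for (th in thr) {
      go_true <- xv >= th # rule: x >= th
      n_true <- sum(go_true[obs]); n_false <- sum(!go_true[obs])
      missing_side <- if (n_true >= n_false) "true" else "false"
      go_true[!obs] <- missing_side == "true"
      if (sum(go_true) < min_leaf || sum(!go_true) < min_leaf) next
      sc <- split_score(y[go_true], y[!go_true], criterion)
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, variable = v, threshold = th,
                     missing_to = missing_side, go_true = go_true)
      }
    }
  }
  best
}

#' Learn a decision tree
#'
#' Greedy top-down induction with either a Pearson chi-square split
#' statistic or the Gini impurity decrease as the splitting criterion.
#' Missing feature values are sent with the majority branch during
#' training and the chosen side is recorded per node, giving the same
#' explicit missing-value routing the reference trees use. The
#' procedure is deterministic for fixed inputs; `seed` is accepted for
#' interface symmetry with the stochastic learners.
#'
#' @param dataset data.frame of numeric features plus a two-level
#'   `target` column.
#' @param criterion `"chi_square"` (split only when the statistic
#'   exceeds the 0.05 critical value, 3.84) or `"gini"` (split while
#'   the impurity decrease is positive).
#' @param max_depth maximum number of rule levels (root = depth 1).
#' @param min_leaf minimum samples per leaf.
#' @param seed unused; kept for a uniform learner interface.
#' @param target_col name of the target column.
#' @return a `vs_tree` whose leaves carry the training class fraction
#'   (`prob_yes`) for score-based metrics.
#' @export
learn_tree <- function(dataset, criterion = c("chi_square", "gini"),
                       max_depth = 6, min_leaf = 5, seed = NULL,
                       target_col = "target") {
  criterion <- match.arg(criterion)
  stopifnot(target_col %in% names(dataset))
  y <- as_binary01(dataset[[target_col]])
  x <- dataset[, setdiff(names(dataset), c(target_col, "patient_id")), drop = FALSE]
  if (!all(vapply(x, is.numeric, TRUE))) stop("features must be numeric")
  if (length(y) == 0) stop("learn_tree: empty data set")
  min_stat <- if (criterion == "chi_square") stats::qchisq(0.95, 1) else 0

  next_id <- 1L
  # breadth-first worklist: pop front, append children in discovery
  # order (false side first, matching the reference-tree layout)
  pending <- list(list(idx = seq_along(y), depth = 1L, slot = NULL))
  assigned <- list() # node_id -> node fields

  make_leaf <- function(idx) {
    p <- mean(y[idx])
    list(variable = NA_character_, comparator = NA_character_,
         threshold = NA_real_, true_child = NA_real_, false_child = NA_real_,
         missing_to = NA_character_,
         leaf_decision = if (p >= 0.5) "Yes" else "No",
         n = length(idx), prob_yes = p)
  }

  while (length(pending)) {
    task <- pending[[1]]; pending <- pending[-1]
    id <- next_id; next_id <- next_id + 1L
    idx <- task$idx
    node <- NULL
    pure <- length(unique(y[idx])) == 1
    if (!pure && task$depth <= max_depth && length(idx) >= 2 * min_leaf) {
      bs <- best_split(x[idx, , drop = FALSE], y[idx], criterion, min_leaf)
      if (is.finite(bs$score) && bs$score > min_stat) {
        # internal nodes keep their training class fraction so pruning
        # can collapse them into majority leaves later
        node <- list(variable = bs$variable, comparator = ">=",
                     threshold = bs$threshold, true_child = NA_real_,
                     false_child = NA_real_, missing_to = bs$missing_to,
                     leaf_decision = NA_character_, n = length(idx),
                     prob_yes = mean(y[idx]))
        pending <- c(pending, list(
          list(idx = idx[!bs$go_true], depth = task$depth + 1L,
               slot = list(parent = id, side = "false")),
          list(idx = idx[bs$go_true], depth = task$depth + 1L,
               slot = list(parent = id, side = "true"))))
      }
    }
    if (is.null(node)) node <- make_leaf(idx)
    assigned[[as.character(id)]] <- node
    if (!is.null(task$slot)) {
      p <- as.character(task$slot$parent)
      side <- if (task$slot$side == "true") "true_child" else "false_child"
      assigned[[p]][[side]] <- id
    }
  }

  nodes <- do.call(rbind, lapply(names(assigned), function(k) {
    nd <- assigned[[k]]
    data.frame(node_id = as.integer(k), n = nd$n, variable = nd$variable,
               comparator = nd$comparator, threshold = nd$threshold,
               true_child = nd$true_child, false_child = nd$false_child,
               missing_to = nd$missing_to, leaf_decision = nd$leaf_decision,
               prob_yes = nd$prob_yes, stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$node_id), ]
  decision_tree(nodes, root = 1L,
                name = paste0("learned (", criterion, ")"))
}

#' Reduced-error pruning on a validation set
#'
#' Bottom-up pruning of a learned tree against held-out data, matching
#' the study design in which the training partition grows the model and
#' the validation partition optimizes it. Each internal node is
#' replaced by a majority leaf (its training class fraction decides the
#' label) whenever doing so does not increase the number of validation
#' errors among the records reaching that node; ties prune, favoring
#' the simpler tree.
#'
#' @param tree a `vs_tree` from [learn_tree()] (internal nodes must
#'   carry `prob_yes`, the training class fraction).
#' @param dataset validation data.frame with the tree's feature columns
#'   and a two-level target column.
#' @param target_col name of the target column.
#' @return the pruned `vs_tree`.
#' @export
prune_tree <- function(tree, dataset, target_col = "target") {
  stopifnot(inherits(tree, "vs_tree"))
  y <- as_binary01(dataset[[target_col]])
  if (length(y) == 0) return(tree)
  nodes <- tree$nodes
  # which validation rows reach each node
  reach <- setNames(vector("list", nrow(nodes)), nodes$node_id)
  for (i in seq_len(nrow(dataset))) {
    tr <- route(tree, as.list(dataset[i, , drop = FALSE]))
    for (id in tr$path) {
      k <- as.character(id)
      reach[[k]] <- c(reach[[k]], i)
    }
  }
  internal <- nodes$node_id[is.na(nodes$leaf_decision)]
  depths <- vapply(internal, function(id) {
    # distance from root
    path_len <- 0; cur <- id
    parent_of <- function(child) {
      hit <- nodes$node_id[!is.na(nodes$true_child) &
                             (nodes$true_child == child | nodes$false_child == child)]
      if (length(hit)) hit else NA_integer_
    }
    while (!is.na(cur) && cur != tree$root) { cur <- parent_of(cur); path_len <- path_len + 1 }
    path_len
  }, 0)

  pruned <- nodes
  for (id in internal[order(depths, decreasing = TRUE)]) {
    k <- as.character(id)
    if (!is.na(pruned$leaf_decision[match(id, pruned$node_id)])) next
    idx <- reach[[k]]
    if (is.null(idx)) idx <- integer(0)
    maj <- if (pruned$prob_yes[match(id, pruned$node_id)] >= 0.5) "Yes" else "No"
    if (length(idx)) {
      cur_tree <- decision_tree(pruned, root = tree$root, name = tree$name)
      sub_err <- sum(vapply(idx, function(i) {
        route(cur_tree, as.list(dataset[i, , drop = FALSE]))$decision
      }, "") != ifelse(y[idx] == 1, "Yes", "No"))
      leaf_err <- sum(maj != ifelse(y[idx] == 1, "Yes", "No"))
    } else {
      sub_err <- 0; leaf_err <- 0 # no validation evidence: simplify
    }
    if (leaf_err <= sub_err) {
      # collapse: drop the whole subtree below id
      drop_ids <- integer(0)
      stack <- c(pruned$true_child[match(id, pruned$node_id)],
                 pruned$false_child[match(id, pruned$node_id)])
      while (length(stack)) {
        cur <- stack[1]; stack <- stack[-1]
        if (is.na(cur)) next
        drop_ids <- c(drop_ids, cur)
        r <- match(cur, pruned$node_id)
        stack <- c(stack, pruned$true_child[r], pruned$false_child[r])
      }
      r <- match(id, pruned$node_id)
      pruned$leaf_decision[r] <- maj
      pruned$variable[r] <- NA_character_
      pruned$comparator[r] <- NA_character_
      pruned$threshold[r] <- NA_real_
      pruned$true_child[r] <- NA_real_
      pruned$false_child[r] <- NA_real_
      pruned$missing_to[r] <- NA_character_
      pruned <- pruned[!pruned$node_id %in% drop_ids, , drop = FALSE]
    }
  }
  decision_tree(pruned, root = tree$root, name = paste0(tree$name, ", pruned"))
}
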