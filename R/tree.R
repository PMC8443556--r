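# Binary decision trees with explicit missing-value routing.
#
# A node rule is (variable, comparator, threshold); when the rule
# evaluates TRUE descent continues to `true_child`, else to
# `false_child`. A missing input routes to the side named by
# `missing_to` ("true", "false", or "none" -- in which case routing is a
# hard error naming the node and variable, rather than a silent guess).

#' Construct a decision tree from a node table
#'
#' @param nodes data.frame with columns `node_id` (unique integers),
#'   `n` (optional training sample count, `NA` allowed), `variable`,
#'   `comparator` (one of `">="`, `"<"`, `"=="`), `threshold`,
#'   `true_child`, `false_child`, `missing_to` (`"true"`, `"false"` or
#'   `"none"`), `leaf_decision` (`"Yes"`/`"No"` for leaves, `NA` for
#'   internal nodes) and optionally `prob_yes` (leaf score in \[0,1\]).
#' @param root id of the root node (default: first row).
#' @param name free-text tree label.
#' @return a `vs_tree`.
#' @export
decision_tree <- function(nodes, root = nodes$node_id[1], name = "tree") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("node_id", "variable", "comparator", "threshold",
            "true_child", "false_child", "missing_to", "leaf_decision")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) stop("decision_tree: missing column(s): ", paste(miss, collapse = ", "))
  if (!"n" %in% names(nodes)) nodes$n <- NA_real_
  if (!"prob_yes" %in% names(nodes)) nodes$prob_yes <- NA_real_
  nodes$node_id <- as.integer(nodes$node_id)
  if (anyDuplicated(nodes$node_id)) stop("decision_tree: duplicate node ids")

  is_leaf <- !is.na(nodes$leaf_decision)
  has_kids <- !is.na(nodes$true_child) & !is.na(nodes$false_child)
  if (any(is_leaf & has_kids) || any(!is_leaf & !has_kids)) {
    stop("decision_tree: every node must be either a leaf (decision, no ",
         "children) or internal (both children, no decision)")
  }
  if (any(!is_leaf & !nodes$comparator %in% c(">=", "<", "=="))) {
    stop("decision_tree: comparator must be '>=', '<' or '=='")
  }
  if (any(!is_leaf & !nodes$missing_to %in% c("true", "false", "none"))) {
    stop("decision_tree: missing_to must be 'true', 'false' or 'none'")
  }
  kids <- c(nodes$true_child[!is_leaf], nodes$false_child[!is_leaf])
  if (anyDuplicated(kids)) stop("decision_tree: a node has more than one parent")
  if (root %in% kids) stop("decision_tree: root cannot be a child")
  if (!setequal(c(root, kids), nodes$node_id)) {
    stop("decision_tree: children must reference existing nodes and every ",
         "non-root node must be some node's child")
  }
  structure(list(nodes = nodes, root = as.integer(root), name = name),
            class = "vs_tree")
}

node_row <- function(tree, id) tree$nodes[match(id, tree$nodes$node_id), ]

#' Variables referenced by a tree's rules
#' @param tree a `vs_tree`.
#' @return character vector of variable names.
#' @export
tree_variables <- function(tree) {
  unique(tree$nodes$variable[is.na(tree$nodes$leaf_decision)])
}

#' Route a feature vector through a decision tree
#'
#' Deterministic root-to-leaf descent. At each internal node the rule
#' `variable comparator threshold` is evaluated (`>=` and `<` are
#' threshold-inclusive exactly as written, `==` is exact equality);
#' TRUE continues to the true child, FALSE to the false child, and a
#' missing input to the node's `missing_to` side. Variables absent from
#' the tree's rules are never inspected.
#'
#' @param tree a `vs_tree`.
#' @param features named list or numeric vector; variables may be
#'   absent or `NA` (both count as missing).
#' @return a `vs_trace`: list with `path` (visited node ids), `decision`
#'   (`"Yes"`/`"No"`), `prob_yes` (leaf score or `NA`) and `inputs_used`
#'   (variables actually inspected).
#' @export
route <- function(tree, features) {
  stopifnot(inherits(tree, "vs_tree"))
  features <- as.list(features)
  id <- tree$root
  path <- integer(0)
  used <- character(0)
  repeat {
    nd <- node_row(tree, id)
    path <- c(path, id)
    if (!is.na(nd$leaf_decision)) {
      return(structure(list(path = path, decision = nd$leaf_decision,
                            prob_yes = nd$prob_yes, inputs_used = unique(used)),
                       class = "vs_trace"))
    }
    used <- c(used, nd$variable)
    val <- features[[nd$variable]]
    if (is.null(val) || is.na(val)) {
      if (nd$missing_to == "none") {
        stop("routing error at node ", nd$node_id, ": variable '",
             nd$variable, "' is missing and the node has no N/A side")
      }
      go_true <- nd$missing_to == "true"
    } else {
      go_true <- switch(nd$comparator,
                        ">=" = val >= nd$threshold,
                        "<"  = val <  nd$threshold,
                        "==" = val == nd$threshold)
    }
    id <- if (go_true) nd$true_child else nd$false_child
  }
}

#' @export
print.vs_trace <- function(x, ...) {
  cat("<vs_trace> path: ", paste(x$path, collapse = " -> "),
      "; decision: ", x$decision, "\n", sep = "")
  invisible(x)
}

#' @export
print.vs_tree <- function(x, ...) {
  cat("<vs_tree> '", x$name, "', ", nrow(x$nodes), " nodes (",
      sum(!is.na(x$nodes$leaf_decision)), " leaves)\n", sep = "")
  nd <- x$nodes
  rule <- ifelse(is.na(nd$leaf_decision),
                 paste0(nd$variable, " ", nd$comparator, " ", nd$threshold,
                        ifelse(nd$missing_to == "true", " or N/A",
                               ifelse(nd$missing_to == "false", " (N/A -> false)", ""))),
                 nd$leaf_decision)
  print(data.frame(node_id = nd$node_id, n = nd$n, rule = rule,
                   false_child = nd$false_child, true_child = nd$true_child))
  invisible(x)
}

#' Predict with a decision tree
#'
#' @param object a `vs_tree`.
#' @param newdata data.frame of feature columns.
#' @param type `"class"` for `Yes`/`No` labels, `"prob"` for the leaf
#'   score (training fraction of `Yes`; for reference trees without
#'   stored scores the 0/1 class indicator is returned instead).
#' @param ... unused.
#' @return factor (levels `No`, `Yes`) or numeric vector.
#' @export
predict.vs_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  traces <- lapply(seq_len(nrow(newdata)), function(i) {
    route(object, as.list(newdata[i, , drop = FALSE]))
  })
  if (type == "class") {
    factor(vapply(traces, `[[`, "", "decision"), levels = c("No", "Yes"))
  } else {
    vapply(traces, function(tr) {
      if (is.na(tr$prob_yes)) as.numeric(tr$decision == "Yes") else tr$prob_yes
    }, 0)
  }
}

#' Published reference tree for the static (CBR) track
#'
#' The published 13-node tree over the five expert static variables.
#' Rules printed with "or N/A" route missing values to their true side;
#' the remaining rules have no N/A side and raise a routing error on
#' missing input. Node sample counts are the published training counts,
#' kept as annotations only.
#'
#' @return a `vs_tree`.
#' @export
cbr_reference_tree <- function() {
  nodes <- data.frame(
    node_id  = 1:13,
    n        = c(184, 61, 123, 9, 52, 86, 37, 17, 69, 39, 30, 18, 12),
    variable = c("PTA_VS_SR8", "SRT", "PTA_H_SR8", NA, NA, "PTA_D_AR4", NA,
                 NA, "PTA_VS_SR8", NA, "Koos", NA, NA),
    comparator = c(">=", ">=", ">=", NA, NA, ">=", NA, NA, ">=", NA, "==", NA, NA),
    threshold  = c(2.3, 27.5, 6.7, NA, NA, 18.1, NA, NA, 7.1, NA, 2, NA, NA),
    true_child  = c(3, 5, 7, NA, NA, 9, NA, NA, 11, NA, 13, NA, NA),
    false_child = c(2, 4, 6, NA, NA, 8, NA, NA, 10, NA, 12, NA, NA),
    missing_to  = c("true", "true", "none", NA, NA, "true", NA, NA, "none",
                    NA, "none", NA, NA),
    leaf_decision = c(NA, NA, NA, "No", "Yes", NA, "No", "Yes", NA, "No",
                      NA, "No", "Yes"),
    stringsAsFactors = FALSE
  )
  decision_tree(nodes, root = 1L, name = "CBR reference tree")
}

#' Published reference tree for the dynamic (PDA) track
#'
#' The published 5-node tree: any increase of the Koos grade since the
#' previous checkup (`Koos_LD >= 0.01`, i.e. any positive last
#' difference) recommends active treatment; with Koos unchanged, a
#' fitted size growth of at least 0.0064 mm/day (about 2.3 mm/year)
#' recommends active treatment; otherwise wait-and-scan continues.
#'
#' @return a `vs_tree`.
#' @export
pda_reference_tree <- function() {
  nodes <- data.frame(
    node_id  = 1:5,
    n        = c(42, 31, 11, 24, 7),
    variable = c("Koos_LD", "Size_SC", NA, NA, NA),
    comparator = c("<", "<", NA, NA, NA),
    threshold  = c(0.01, 0.0064, NA, NA, NA),
    true_child  = c(2, 4, NA, NA, NA),
    false_child = c(3, 5, NA, NA, NA),
    missing_to  = c("none", "none", NA, NA, NA),
    leaf_decision = c(NA, NA, "Yes", "No", "Yes"),
    stringsAsFactors = FALSE
  )
  decision_tree(nodes, root = 1L, name = "PDA reference tree")
}

#' Serialize a decision tree to JSON
#'
#' The node list mirrors the tabular form of the tree (id, sample
#' count, rule, children, missing side, leaf decision).
#'
#' @param tree a `vs_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  payload <- list(name = tree$name, root = tree$root, nodes = tree$nodes)
  jsonlite::write_json(payload, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a decision tree from JSON
#'
#' @param path file written by [write_tree_json()].
#' @return a `vs_tree`.
#' @export
read_tree_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- payload$nodes
  for (col in c("variable", "comparator", "missing_to", "leaf_decision")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_character_
    nodes[[col]] <- as.character(nodes[[col]])
  }
  for (col in c("threshold", "true_child", "false_child", "n", "prob_yes")) {
    if (!col %in% names(nodes)) nodes[[col]] <- NA_real_
    nodes[[col]] <- as.numeric(nodes[[col]])
  }
  decision_tree(nodes, root = payload$root, name = payload$name)
}

#' Render a decision tree as Graphviz DOT
#'
#' @param tree a `vs_tree`.
#' @param path optional file to write to.
#' @return the DOT source as a character scalar (invisibly when `path`
#'   is given).
#' @export
tree_to_dot <- function(tree, path = NULL) {
  nd <- tree$nodes
  lines <- c(paste0("digraph \"", tree$name, "\" {"),
             "  node [shape=box];")
  for (i in seq_len(nrow(nd))) {
    r <- nd[i, ]
    lab <- if (!is.na(r$leaf_decision)) {
      paste0(r$leaf_decision, if (!is.na(r$n)) paste0("\\nn=", r$n))
    } else {
      paste0(r$variable, " ", r$comparator, " ", r$threshold,
             if (r$missing_to == "true") " or N/A",
             if (!is.na(r$n)) paste0("\\nn=", r$n))
    }
    lines <- c(lines, paste0("  n", r$node_id, " [label=\"", lab, "\"];"))
    if (is.na(r$leaf_decision)) {
      lines <- c(lines,
                 paste0("  n", r$node_id, " -> n", r$true_child, " [label=\"yes\"];"),
                 paste0("  n", r$node_id, " -> n", r$false_child, " [label=\"no\"];"))
    }
  }
  dot <- paste(c(lines, "}"), collapse = "\n")
  if (!is.null(path)) {
    writeLines(dot, path)
    return(invisible(dot))
  }
  dot
}
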