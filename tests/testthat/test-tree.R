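test_that("the static reference tree has the published structure", {
  tr <- cbr_reference_tree()
  expect_equal(nrow(tr$nodes), 13)
  expect_equal(sum(!is.na(tr$nodes$leaf_decision)), 7)
  root <- tr$nodes[tr$nodes$node_id == 1, ]
  expect_equal(root$variable, "PTA_VS_SR8")
  expect_equal(root$threshold, 2.3)
  expect_equal(root$missing_to, "true")
  expect_equal(tr$nodes$leaf_decision[tr$nodes$node_id == 5], "Yes")
  expect_equal(tr$nodes$n[tr$nodes$node_id == 5], 52)
  expect_setequal(tree_variables(tr),
                  c("PTA_VS_SR8", "SRT", "PTA_H_SR8", "PTA_D_AR4", "Koos"))
})

test_that("routing reproduces all published worked inferences exactly", {
  tr <- cbr_reference_tree()
  for (rec in table4_records()) {
    trace <- route(tr, rec$f)
    expect_equal(trace$path, rec$path)
    expect_equal(trace$decision, rec$pred)
  }
})

test_that("missing values follow the printed N/A sides", {
  tr <- cbr_reference_tree()
  # the root rule carries an N/A side: missing slope goes to its true side
  trace <- route(tr, list(Koos = 2, SRT = 110, PTA_H_SR8 = 7.6, PTA_D_AR4 = 43.8))
  expect_equal(trace$path[1:2], c(1, 3))
  # NA value behaves the same as an absent variable
  trace2 <- route(tr, list(PTA_VS_SR8 = NA, Koos = 2, SRT = 110,
                           PTA_H_SR8 = 7.6, PTA_D_AR4 = 43.8))
  expect_equal(trace2$path, trace$path)
  # nodes printed without an N/A clause refuse missing input, naming both
  # the node and the variable
  expect_error(route(tr, list(PTA_VS_SR8 = 5, SRT = 30, PTA_D_AR4 = 5)),
               "node 3.*PTA_H_SR8")
})

test_that("the dynamic reference tree matches the published decision logic", {
  tr <- pda_reference_tree()
  expect_equal(nrow(tr$nodes), 5)
  # any Koos increase since the previous checkup -> active treatment
  expect_equal(route(tr, list(Koos_LD = 1, Size_SC = 0))$decision, "Yes")
  expect_equal(route(tr, list(Koos_LD = 2, Size_SC = -0.01))$decision, "Yes")
  # Koos unchanged: the size trend decides
  yes <- route(tr, list(Koos_LD = 0, Size_SC = 0.01))
  expect_equal(yes$decision, "Yes")
  expect_equal(yes$path, c(1, 2, 5))
  no <- route(tr, list(Koos_LD = 0, Size_SC = 0))
  expect_equal(no$decision, "No")
  expect_equal(no$path, c(1, 2, 4))
})

test_that("every leaf of both reference trees is reachable", {
  cases_cbr <- list(
    list(PTA_VS_SR8 = 1, SRT = 10, PTA_H_SR8 = 0, PTA_D_AR4 = 0, Koos = 1),   # 4
    list(PTA_VS_SR8 = 1, SRT = 50, PTA_H_SR8 = 0, PTA_D_AR4 = 0, Koos = 1),   # 5
    list(PTA_VS_SR8 = 5, SRT = 50, PTA_H_SR8 = 9, PTA_D_AR4 = 0, Koos = 1),   # 7
    list(PTA_VS_SR8 = 5, SRT = 50, PTA_H_SR8 = 0, PTA_D_AR4 = 5, Koos = 1),   # 8
    list(PTA_VS_SR8 = 5, SRT = 50, PTA_H_SR8 = 0, PTA_D_AR4 = 30, Koos = 1),  # 10
    list(PTA_VS_SR8 = 9, SRT = 50, PTA_H_SR8 = 0, PTA_D_AR4 = 30, Koos = 1),  # 12
    list(PTA_VS_SR8 = 9, SRT = 50, PTA_H_SR8 = 0, PTA_D_AR4 = 30, Koos = 2))  # 13
  tr <- cbr_reference_tree()
  leaves_hit <- sort(unique(vapply(cases_cbr, function(f) {
    p <- route(tr, f)$path
    p[length(p)]
  }, 0)))
  expect_equal(leaves_hit,
               sort(tr$nodes$node_id[!is.na(tr$nodes$leaf_decision)]))

  tr2 <- pda_reference_tree()
  cases_pda <- list(list(Koos_LD = 1, Size_SC = 0),
                    list(Koos_LD = 0, Size_SC = 0),
                    list(Koos_LD = 0, Size_SC = 0.01))
  leaves2 <- sort(unique(vapply(cases_pda, function(f) {
    p <- route(tr2, f)$path
    p[length(p)]
  }, 0)))
  expect_equal(leaves2,
               sort(tr2$nodes$node_id[!is.na(tr2$nodes$leaf_decision)]))
})

test_that("route only inspects variables named in the tree's rules", {
  tr <- pda_reference_tree()
  trace <- route(tr, list(Koos_LD = 0, Size_SC = 0, SDS = 80, bogus = 1))
  expect_true(all(trace$inputs_used %in% tree_variables(tr)))
  # an irrelevant missing variable cannot cause a routing error
  expect_silent(route(tr, list(Koos_LD = 1, Size_SC = NA)))
})

test_that("threshold comparisons are inclusive exactly as written", {
  tr <- cbr_reference_tree()
  at <- route(tr, list(PTA_VS_SR8 = 2.3, SRT = 27.5, PTA_H_SR8 = 0, PTA_D_AR4 = 0, Koos = 1))
  expect_equal(at$path[2], 3) # 2.3 >= 2.3 holds on the true side
  tr2 <- pda_reference_tree()
  at2 <- route(tr2, list(Koos_LD = 0, Size_SC = 0.0064))
  expect_equal(at2$decision, "Yes") # 0.0064 < 0.0064 is false -> growth side
})

test_that("trees serialize to JSON and DOT and back", {
  tr <- cbr_reference_tree()
  path <- withr::local_tempfile(fileext = ".json")
  write_tree_json(tr, path)
  tr2 <- read_tree_json(path)
  expect_equal(tr2$nodes, tr$nodes)
  expect_equal(tr2$root, tr$root)
  for (rec in table4_records()) {
    expect_equal(route(tr2, rec$f)$path, rec$path)
  }
  dot <- tree_to_dot(tr)
  expect_match(dot, "digraph")
  expect_match(dot, "PTA_VS_SR8 >= 2.3 or N/A", fixed = TRUE)
  expect_equal(length(gregexpr("->", dot)[[1]]), 12) # one edge per child link
})

test_that("malformed node tables are rejected", {
  nd <- cbr_reference_tree()$nodes
  dup <- nd; dup$node_id[2] <- 1
  expect_error(decision_tree(dup), "duplicate")
  both <- nd; both$leaf_decision[1] <- "Yes"
  expect_error(decision_tree(both), "leaf")
  two_parents <- nd; two_parents$false_child[2] <- 6
  expect_error(decision_tree(two_parents), "parent")
})

test_that("predict routes whole data frames with class or score output", {
  tr <- pda_reference_tree()
  nd <- data.frame(Koos_LD = c(0, 0, 1), Size_SC = c(0, 0.01, -0.1))
  expect_equal(as.character(predict(tr, nd)), c("No", "Yes", "Yes"))
  # reference trees carry no training fractions: scores fall back to 0/1
  expect_equal(predict(tr, nd, type = "prob"), c(0, 1, 1))
})
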