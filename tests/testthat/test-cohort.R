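test_that("read_cohort parses, groups and sorts checkup records", {
  df <- rbind(
    checkup_row("P2", 300),
    checkup_row("P1", 0),
    checkup_row("P2", 0, Koos = 1) # out of time order relative to first P2 row
  )
  df$SRT[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "N/A")
  co <- read_cohort(path)
  expect_s3_class(co, "vs_cohort")
  expect_equal(nrow(co), 3)
  expect_equal(length(patient_histories(co)), 2)
  expect_true(is.na(co$SRT[co$patient_id == "P1"]))
  p2 <- co[co$patient_id == "P2", ]
  expect_equal(p2$t, sort(p2$t))
  expect_equal(p2$Koos, c(1, 2)) # values follow their rows through the sort
})

test_that("read_cohort reports unparseable numeric cells as missing", {
  df <- checkup_row("P1", 0)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  txt <- readLines(path)
  txt[2] <- sub("45", "forty-five", txt[2]) # corrupt the SRT cell
  writeLines(txt, path)
  expect_message(co <- read_cohort(path), "unparseable")
  expect_true(is.na(co$SRT[1]))
  expect_equal(attr(co, "parse_log")$unparseable_cells, 1L)
})

test_that("read_cohort signals schema and integrity errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(patient_id = "A", t = 0), path, row.names = FALSE)
  expect_error(read_cohort(path), "schema error")
  dup <- rbind(checkup_row("A", 0), checkup_row("A", 0))
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dup, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "integrity error")
})

test_that("schema mapping renames file columns to canonical names", {
  df <- checkup_row("P1", 0)
  names(df)[names(df) == "patient_id"] <- "subject"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  co <- read_cohort(path, schema = c(patient_id = "subject"))
  expect_equal(co$patient_id, "P1")
})

test_that("cohort CSV round-trips all present values exactly", {
  df <- rbind(checkup_row("A", 0, Size = 10.123456789012, SRT = 47.25),
              checkup_row("A", 417, Size = 11.000000001, SRT = NA))
  co <- as_cohort(df)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  for (col in setdiff(cohort_columns(), c("patient_id", "decision"))) {
    expect_identical(co2[[col]], co[[col]], label = col)
  }
  expect_identical(co2$patient_id, co$patient_id)
  expect_identical(co2$decision, co$decision)
})

test_that("clean_complete keeps only complete records, never imputing", {
  rows <- do.call(rbind, lapply(1:10, function(i) checkup_row("P", (i - 1) * 100)))
  rows$SRT[c(2, 5, 9)] <- NA
  co <- as_cohort(rows)
  expect_message(kept <- clean_complete(co, "SRT"), "removed 3")
  expect_equal(nrow(kept), 7)
  expect_identical(kept$SRT, rep(45, 7))
  # idempotent: a second pass removes nothing and changes nothing
  expect_message(again <- clean_complete(kept, "SRT"), "removed 0")
  expect_equal(as.data.frame(again), as.data.frame(kept), ignore_attr = TRUE)
  # vacuous filter
  same <- clean_complete(co, character(0))
  expect_equal(nrow(same), 10)
  # cohort with nothing missing is untouched
  full <- as_cohort(do.call(rbind, lapply(1:4, function(i) checkup_row("Q", i * 10))))
  expect_message(kept_full <- clean_complete(full, cohort_columns()), "removed 0")
  expect_equal(as.data.frame(kept_full), as.data.frame(full), ignore_attr = TRUE)
})

test_that("clean_complete signals an explicitly empty result", {
  rows <- checkup_row("P", 0)
  rows$SDS <- NA
  co <- as_cohort(rows)
  expect_warning(
    suppressMessages(out <- clean_complete(co, "SDS")),
    class = "vsdss_empty_cohort")
  expect_equal(nrow(out), 0)
})

test_that("ceiling measurements are flagged present values, not missing", {
  row <- checkup_row("P", 0, SRT = 110)
  co <- as_cohort(row)
  fl <- ceiling_flags(co)
  expect_true(fl[1, "SRT"])
  expect_false(any(fl[1, colnames(fl) != "SRT"]))
  # a ceiling value survives complete-record cleaning
  kept <- suppressMessages(clean_complete(co, "SRT"))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$SRT, 110)
  expect_true(ceiling_flags(kept)[1, "SRT"])
})

test_that("cohort invariants are enforced", {
  bad_koos <- checkup_row("A", 0, Koos = 5)
  expect_error(as_cohort(bad_koos), "Koos")
  bad_dec <- rbind(checkup_row("A", 0, decision = "Active"), checkup_row("A", 100))
  expect_error(as_cohort(bad_dec), "Active")
  two_active <- rbind(checkup_row("A", 0, decision = "Active"),
                      checkup_row("A", 100, decision = "Active"))
  expect_error(as_cohort(two_active), "Active")
  bad_range <- checkup_row("A", 0, SDS = 140)
  expect_error(as_cohort(bad_range), "percentage")
})

test_that("patient outcomes derive from the final decision", {
  co <- tiny_cohort()
  oc <- patient_outcomes(co)
  expect_equal(oc$outcome[oc$patient_id == "A"], "WaS")
  expect_equal(oc$outcome[oc$patient_id == "B"], "Active")
  expect_equal(oc$n_checkups, c(3L, 2L))
})

test_that("day/month conversion round-trips", {
  expect_equal(months_to_days(days_to_months(1234)), 1234)
  expect_equal(days_to_months(365.25), 12)
})
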