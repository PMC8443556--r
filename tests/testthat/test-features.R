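test_that("pta_average follows range definitions and the completeness rule", {
  flat <- make_audiogram(rep(40, 8))
  expect_equal(pta_average(flat, "full"), 40)
  stepped <- make_audiogram(c(10, 10, 20, 20, 30, 30, 90, 100))
  expect_equal(pta_average(stepped, "basic"), 20)
  # one in-range missing threshold poisons the range, no partial means
  miss3 <- make_audiogram(c(10, 10, 20, 20, NA, 30, 40, 50))
  expect_true(is.na(pta_average(miss3, "basic")))
  miss6 <- make_audiogram(c(10, 10, 20, 20, 30, 30, NA, 50))
  expect_equal(pta_average(miss6, "basic"), 20) # 6 kHz is outside the basic range
  expect_true(is.na(pta_average(miss6, "full")))
  expect_error(pta_average(flat, "broad"), "range_id")
})

test_that("pta_average and pta_linfit ignore frequency-map order", {
  set.seed(42)
  ag <- make_audiogram(round(runif(8, 0, 80)))
  shuffled <- ag[sample(8)]
  expect_equal(pta_average(shuffled, "full"), pta_average(ag, "full"))
  expect_equal(pta_linfit(shuffled, "full"), pta_linfit(ag, "full"))
})

test_that("pta_linfit matches the normal-equations oracle", {
  flat <- make_audiogram(rep(55, 8))
  expect_equal(pta_linfit(flat, "full"),
               c(slope = 0, intercept = 55))
  freqs <- c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
  line <- make_audiogram(5 + 10 * freqs)
  expect_equal(pta_linfit(line, "full"), c(slope = 10, intercept = 5))
  # non-collinear audiogram against closed-form least squares
  set.seed(7)
  ag <- make_audiogram(20 + 5 * freqs + rnorm(8, 0, 10))
  for (rid in c("basic", "full")) {
    f <- if (rid == "basic") freqs[1:6] else freqs
    ora <- ols_oracle(f, as.numeric(ag[seq_along(f)]))
    got <- pta_linfit(ag, rid)
    expect_equal(got[["slope"]], ora[["slope"]], tolerance = 1e-9)
    expect_equal(got[["intercept"]], ora[["intercept"]], tolerance = 1e-9)
  }
  # alternative abscissas change units but stay exact on constructed lines
  oct_line <- make_audiogram(30 + 6 * log2(freqs))
  expect_equal(pta_linfit(oct_line, "full", abscissa = "log2khz"),
               c(slope = 6, intercept = 30))
  idx_line <- make_audiogram(10 + 2 * (1:8))
  expect_equal(pta_linfit(idx_line, "full", abscissa = "index"),
               c(slope = 2, intercept = 10))
  miss <- make_audiogram(c(NA, rep(20, 7)))
  expect_true(all(is.na(pta_linfit(miss, "basic"))))
})

test_that("column_summary computes the temporal metrics exactly", {
  cs <- column_summary(c(0, 100, 200), c(10, 11, 12))
  expect_equal(cs, c(AC = 11, SC = 0.01, IC = 10, LD = 1, TD = 2))
  single <- column_summary(0, 3)
  expect_equal(single[["AC"]], 3)
  expect_equal(single[["IC"]], 3)
  expect_equal(single[["TD"]], 0)
  expect_true(is.na(single[["SC"]]) && is.na(single[["LD"]]))
  # random series against the normal-equations oracle
  set.seed(11)
  t <- sort(sample(0:2000, 6))
  v <- rnorm(6, 20, 5)
  cs <- column_summary(t, v)
  ora <- ols_oracle(t, v)
  expect_equal(cs[["SC"]], ora[["slope"]], tolerance = 1e-9)
  expect_equal(cs[["IC"]], ora[["intercept"]], tolerance = 1e-9)
  expect_error(column_summary(numeric(0), numeric(0)), "empty")
  expect_error(column_summary(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("column_summary time-shift and telescoping properties hold", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    t <- sort(sample(0:3000, n))
    v <- rnorm(n, 15, 4)
    shift <- runif(1, 10, 500)
    a <- column_summary(t, v)
    b <- column_summary(t + shift, v)
    expect_equal(b[["SC"]], a[["SC"]], tolerance = 1e-8)
    expect_equal(b[["AC"]], a[["AC"]])
    expect_equal(b[["LD"]], a[["LD"]])
    expect_equal(b[["TD"]], a[["TD"]])
    expect_equal(b[["IC"]], a[["IC"]] - shift * a[["SC"]], tolerance = 1e-8)
    # total difference telescopes over successive differences
    expect_equal(a[["TD"]], sum(diff(v)))
  }
})

test_that("build_cbr_dataset composes the derived metrics per checkup", {
  set.seed(5)
  vs <- round(runif(8, 20, 90)); h <- round(runif(8, 0, 40))
  co <- as_cohort(rbind(checkup_row("A", 0, vs = vs, h = h),
                        checkup_row("A", 300), checkup_row("A", 700)))
  d <- build_cbr_dataset(co)
  expect_equal(nrow(d), 3)
  expect_setequal(setdiff(names(d), "target"), cbr_feature_names())
  ag_vs <- make_audiogram(vs); ag_h <- make_audiogram(h)
  expect_equal(d$PTA_VS_AR8[1], pta_average(ag_vs, "full"))
  expect_equal(d$PTA_VS_AR4[1], pta_average(ag_vs, "basic"))
  expect_equal(d$PTA_H_SR8[1], pta_linfit(ag_h, "full")[["slope"]])
  expect_equal(d$PTA_VS_IR4[1], pta_linfit(ag_vs, "basic")[["intercept"]])
  expect_equal(d$PTA_D_AR4[1],
               pta_average(ag_vs, "basic") - pta_average(ag_h, "basic"))
  expect_equal(as.character(d$target), c("No", "No", "No"))
  # empty cohort gives an empty, fully-typed frame
  empty <- build_cbr_dataset(as_cohort(checkup_row("Z", 0))[0, ])
  expect_equal(nrow(empty), 0)
  expect_setequal(setdiff(names(empty), "target"), cbr_feature_names())
})

test_that("swapping the ears negates the inter-ear differences", {
  set.seed(9)
  vs <- round(runif(8, 20, 90)); h <- round(runif(8, 0, 40))
  co <- as_cohort(checkup_row("A", 0, vs = vs, h = h))
  swapped <- as_cohort(checkup_row("A", 0, vs = h, h = vs))
  d1 <- build_cbr_dataset(co); d2 <- build_cbr_dataset(swapped)
  expect_equal(d2$PTA_D_AR4, -d1$PTA_D_AR4)
  expect_equal(d2$PTA_D_AR8, -d1$PTA_D_AR8)
})

test_that("build_pda_dataset summarizes each patient's history", {
  rows <- rbind(
    checkup_row("A", 0, Koos = 2, Size = 10),
    checkup_row("A", 300, Koos = 2, Size = 10),
    checkup_row("A", 650, Koos = 3, Size = 10, decision = "Active"),
    checkup_row("B", 0, Koos = 1, Size = 8),
    checkup_row("B", 400, Koos = 1, Size = 8)
  )
  d <- build_pda_dataset(as_cohort(rows))
  a <- d[d$patient_id == "A", ]
  expect_equal(a$Koos_LD, 1)
  expect_equal(a$Koos_TD, 1)
  expect_equal(as.character(a$target), "Yes")
  # constant series has zero slope and differences
  expect_equal(a$Size_SC, 0)
  expect_equal(a$Size_LD, 0)
  expect_equal(a$Size_TD, 0)
  b <- d[d$patient_id == "B", ]
  expect_equal(as.character(b$target), "No")
  expect_equal(b$Size_SC, 0)
})

test_that("build_pda_dataset yields one vector per patient and flags singletons", {
  co <- simulate_cohort(synthetic_config(n_patients = 42, missing_rate = 0),
                        seed = 21)
  d <- build_pda_dataset(co)
  expect_equal(nrow(d), 42)
  expect_true(all(paste0("Koos_", c("AC", "SC", "IC", "LD", "TD")) %in% names(d)))
  single <- as_cohort(checkup_row("S", 0))
  expect_warning(ds <- build_pda_dataset(single), "single checkup")
  expect_true(is.na(ds$Size_SC) && is.na(ds$Size_LD))
  expect_equal(ds$Size_AC, 10)
  expect_equal(ds$Size_TD, 0)
})
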