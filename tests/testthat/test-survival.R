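test_that("km_estimate reproduces the hand product-limit example", {
  # subjects: t=1 censored, t=2 event, t=3 censored, t=4 event
  km <- km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(km$time, c(2, 4))
  expect_equal(km$n_risk, c(3L, 1L))
  expect_equal(km$surv, c(2 / 3, 0), tolerance = 1e-12)
  expect_equal(km$median, 4)

  # all censored: flat curve, median undefined
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(length(km0$time), 0L)
  expect_true(is.na(km0$median))
  expect_equal(km_surv_at(km0, c(0, 10)), c(1, 1))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  expect_error(km_estimate(c(1, 2), c(1, 2)), "binary")
})

test_that("km_estimate equals the empirical survival function without censoring", {
  set.seed(9)
  t <- rexp(40)
  km <- km_estimate(t, rep(1, 40))
  ecdf_surv <- function(x) mean(t > x)
  for (x in quantile(t, c(0.1, 0.5, 0.9)))
    expect_equal(km_surv_at(km, x), ecdf_surv(x), tolerance = 1e-12)
  # duplicating every subject leaves S unchanged
  km2 <- km_estimate(rep(t, 2), rep(1, 80))
  expect_equal(km2$surv, km$surv, tolerance = 1e-12)
})

test_that("km_estimate agrees with the survival package oracle", {
  set.seed(4)
  t <- round(rexp(60), 2)
  e <- rbinom(60, 1, 0.7)
  km <- km_estimate(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  ref_t <- sf$time[sf$n.event > 0]
  ref_s <- sf$surv[sf$n.event > 0]
  ref_se <- sf$std.err[sf$n.event > 0] * ref_s   # survfit reports se(log S)
  expect_equal(km$time, ref_t)
  expect_equal(km$surv, ref_s, tolerance = 1e-9)
  idx <- ref_s > 0 & is.finite(km$se)    # Greenwood degenerates at S = 0
  expect_equal(km$se[idx], ref_se[idx], tolerance = 1e-6)
})

test_that("logrank_test reproduces the hand O/E/V table", {
  # group A events at 1, 2; group B events at 3, 4; no censoring
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(unname(lr$observed["A"]), 2)
  expect_equal(unname(lr$expected["A"]), 5 / 6, tolerance = 1e-12)
  expect_equal(unname(lr$variance["A", "A"]), 17 / 36, tolerance = 1e-12)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-9)   # ~2.882
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  # symmetric single events: statistic 0
  lr0 <- logrank_test(c(1, 1), c(1, 1), c("A", "B"))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
})

test_that("logrank_test matches survdiff and the classic two-group form", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 60
    g <- sample(c("A", "B", "C"), n, replace = TRUE)
    t <- rexp(n, rate = ifelse(g == "A", 1.5, 1))
    e <- rbinom(n, 1, 0.8)
    lr <- logrank_test(t, e, g)
    sd_ref <- survival::survdiff(survival::Surv(t, e) ~ g)
    expect_equal(lr$statistic, sd_ref$chisq, tolerance = 1e-9)
    expect_equal(unname(lr$expected), unname(sd_ref$exp), tolerance = 1e-9)
  }
  # two-group statistic equals (O-E)^2 / V
  g2 <- rep(c("A", "B"), each = 25)
  t2 <- rexp(50); e2 <- rbinom(50, 1, 0.9)
  lr2 <- logrank_test(t2, e2, g2)
  expect_equal(lr2$statistic,
               (lr2$observed["A"] - lr2$expected["A"])^2 / lr2$variance["A", "A"],
               tolerance = 1e-9, ignore_attr = TRUE)
  # invariance to group relabeling
  lr2b <- logrank_test(t2, e2, c(B = "Z", A = "Q")[g2])
  expect_equal(lr2b$statistic, lr2$statistic, tolerance = 1e-12)
})

test_that("stratified_survival joins, drops empty labels and tests across labels", {
  cfg <- cohort_config(n_samples = 200, seed = 5)
  ch <- generate_cohort(cfg)
  lab <- data.frame(sample_id = names(ch$truth_labels),
                    label = unname(ch$truth_labels))
  strat <- stratified_survival(ch$clinical, lab)
  expect_setequal(names(strat$curves), unique(lab$label))
  expect_s3_class(strat$logrank, "LogRankResult")
  expect_true(strat$logrank$p_value < 0.05)  # planted hazards are far apart

  # ordering of group median survival follows planted hazards (ALT worst)
  meds <- vapply(strat$curves, function(k)
    if (is.na(k$median)) Inf else k$median, numeric(1))
  expect_lt(meds[["ALT"]], meds[["NDTMM"]])

  one <- lab[lab$label == "ALT", ][1:5, ]
  expect_error(stratified_survival(ch$clinical, one), "fewer than 2")
})

test_that("outcome_split strategies dichotomize as documented", {
  cl <- data.frame(sample_id = sprintf("s%d", 1:6),
                   os_time = c(10, 50, 100, 200, 300, 400),
                   os_event = c(1, 1, 1, 0, 0, 0),
                   stage = NA_character_, cohort = "X")
  cl <- tmmpipe:::validate_clinical(cl)
  sp <- outcome_split(cl, "median_event")
  # median event time = 50: poor = died before 50, good = censored after 50
  expect_identical(sp$outcome, c("poor", NA, NA, "good", "good", "good"))
  sp2 <- outcome_split(cl, "event")
  expect_identical(sp2$outcome, rep(c("poor", "good"), each = 3))
})
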