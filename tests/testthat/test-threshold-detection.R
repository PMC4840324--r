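test_that("percentile thresholds follow the interpolated order-statistic convention", {
  suppressWarnings(thr <- fit_thresholds(1:100))
  expect_equal(thr$proz_low, 1.99)
  expect_equal(thr$proz_high, 99.01)
  expect_equal(thr$ca125_clinical, 35)

  suppressWarnings(thr_k <- fit_thresholds(rep(7, 50)))
  expect_equal(thr_k$proz_low, 7)
  expect_equal(thr_k$proz_high, 7)

  expect_error(fit_thresholds(1:5), "at least 10")
  expect_warning(fit_thresholds(1:50), "fewer than 100")

  # monotone in the percentile argument
  x <- stats::rlnorm(500)
  a <- fit_thresholds(x, percentiles = c(1, 99))
  b <- fit_thresholds(x, percentiles = c(5, 95))
  expect_lt(a$proz_low, b$proz_low)
  expect_gt(a$proz_high, b$proz_high)
})

test_that("the fitting controls breach their own low threshold about 1% of the time", {
  set.seed(6)
  for (i in 1:5) {
    x <- stats::rlnorm(500, log(1500), 0.3)
    thr <- fit_thresholds(x)
    frac <- mean(x < thr$proz_low)
    expect_gte(frac, 0.005)
    expect_lte(frac, 0.015)
  }
})

test_that("detection uses strict crossings and earliest crossing times", {
  m <- tiny_manifest()
  # T1 has one sample (700 ng/ml) far below; T2 has one (2600) far above
  thr <- structure(list(proz_low = 1000, proz_high = 2000,
                        ca125_clinical = 35, percentiles = c(1, 99),
                        n_control = 100, quantile_type = 7L),
                   class = "threshold_set")
  det <- detect_cases(m, thr)
  t1 <- det[det$subject_id == "T1", ]
  expect_true(t1$detected_by_proz)
  expect_identical(t1$direction, "low")
  expect_equal(t1$first_detection_days, 90)
  expect_false(t1$detected_by_ca125)
  # T1's ROCA-positive sample is at day 90: lead 0
  expect_equal(t1$lead_vs_roca, 0)

  t2 <- det[det$subject_id == "T2", ]
  expect_true(t2$detected_by_proz)
  expect_identical(t2$direction, "high")
  expect_true(t2$detected_by_ca125)       # 80 U/ml > 35
  expect_equal(t2$ca125_first_days, 80)

  # the CA-125 rule is strictly greater than 35
  m2 <- tiny_manifest()
  m2$samples$ca125[m2$samples$subject_id == "T2"] <- c(35, 35)
  m2 <- cohort_manifest(m2$subjects, m2$samples)
  det2 <- detect_cases(m2, thr)
  expect_false(det2$detected_by_ca125[det2$subject_id == "T2"])

  # a case sitting inside the control range is not detected
  thr_wide <- thr
  thr_wide$proz_low <- 1
  thr_wide$proz_high <- 1e6
  det3 <- detect_cases(m, thr_wide)
  expect_true(all(!det3$detected_by_proz))
  expect_true(all(is.na(det3$first_detection_days)))
})

test_that("detected responders cross at the generator's first crossing sample", {
  sim <- simulate_cohort(generator_config(seed = 8))
  m <- sim$manifest
  s <- merge(m$samples, m$subjects[c("subject_id", "group")], by = "subject_id")
  thr <- fit_thresholds(s$proz[s$group == "control"])
  det <- detect_cases(m, thr)
  # brute-force re-derivation of flags and first crossing per subject
  for (i in seq_len(nrow(det))) {
    ss <- m$samples[m$samples$subject_id == det$subject_id[i], ]
    crossing <- if (det$cancer_type[i] == "type1") ss$proz < thr$proz_low
    else ss$proz > thr$proz_high
    expect_identical(det$detected_by_proz[i], any(crossing))
    if (any(crossing)) {
      expect_equal(det$first_detection_days[i],
                   max(ss$days_to_diagnosis[crossing]))
    }
  }
  # responders drive the detections; an occasional non-responder can cross
  # the 1st-percentile tail by chance
  truth <- sim$truth
  detected <- det$subject_id[det$detected_by_proz]
  expect_gt(length(detected), 0)
  expect_gte(mean(truth$responder[match(detected, truth$subject_id)]), 0.8)
})

test_that("lead-time report medians match brute force", {
  res <- data.frame(
    subject_id = c("a", "b", "c", "d"),
    cancer_type = c("type1", "type1", "type2", "type2"),
    detected_by_proz = c(TRUE, TRUE, TRUE, FALSE),
    direction = c("low", "low", "high", NA),
    first_detection_days = c(900, 300, 1100, NA),
    detected_by_ca125 = c(FALSE, TRUE, FALSE, TRUE),
    ca125_first_days = c(NA, 250, NA, 90),
    roca_first_positive_days = c(300, 200, 400, 80),
    lead_vs_roca = c(600, 100, 700, NA),
    n_samples = c(6, 6, 6, 6), stringsAsFactors = FALSE)
  rep <- leadtime_report(res)
  t1 <- rep$per_type[rep$per_type$cancer_type == "type1", ]
  expect_equal(t1$median_first_detection_days, median(c(900, 300)))
  expect_equal(t1$median_lead_vs_roca, median(c(600, 100)))
  expect_identical(t1$proz_only, 1L)
  expect_identical(t1$both, 1L)
  t2 <- rep$per_type[rep$per_type$cancer_type == "type2", ]
  expect_identical(t2$ca125_only, 1L)
  expect_equal(t2$median_first_detection_days, 1100)
})

test_that("exclusivity matrix: null cohorts breach off-type thresholds near 1%", {
  # all effects off: case samples follow the control law, so both breach
  # fractions estimate the percentile tail mass
  cfg <- generator_config(n_control = 400, n_type1 = 400, n_type2 = 400,
                          type1_responder_fraction = 0,
                          type2_responder_fraction = 0, seed = 17)
  m <- simulate_cohort(cfg)$manifest
  s <- merge(m$samples, m$subjects[c("subject_id", "group")], by = "subject_id")
  thr <- fit_thresholds(s$proz[s$group == "control"])
  ex <- exclusivity_matrix(m, thr)
  expect_equal(ex$frac_below_low[ex$cancer_type == "type1"], 0.01,
               tolerance = 0.7)
  expect_equal(ex$frac_above_high[ex$cancer_type == "type2"], 0.01,
               tolerance = 0.7)
  expect_equal(ex$frac_above_high[ex$cancer_type == "type1"], 0.01,
               tolerance = 0.7)

  # no cases: all case cells zero
  m0 <- simulate_cohort(generator_config(n_control = 30, n_type1 = 0,
                                         n_type2 = 0, seed = 2))$manifest
  ex0 <- exclusivity_matrix(m0, thr)
  expect_true(all(ex0$n_samples == 0))
  expect_true(all(ex0$n_below_low == 0 & ex0$n_above_high == 0))
})

test_that("default-cohort exclusivity: responder signals stay on their own side", {
  m <- fixture_cohort()
  s <- merge(m$samples, m$subjects[c("subject_id", "group")], by = "subject_id")
  thr <- fit_thresholds(s$proz[s$group == "control"])
  ex <- exclusivity_matrix(m, thr)
  # Type I points breach the low threshold far more often than Type II do,
  # and vice versa for the high threshold
  expect_gt(ex$frac_below_low[ex$cancer_type == "type1"],
            3 * ex$frac_below_low[ex$cancer_type == "type2"])
  expect_gt(ex$frac_above_high[ex$cancer_type == "type2"],
            ex$frac_above_high[ex$cancer_type == "type1"])
})
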