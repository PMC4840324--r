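test_that("the generator is seed-deterministic and seed-sensitive", {
  cfg <- generator_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest$samples, b$manifest$samples)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(generator_config(seed = 43))
  expect_false(identical(a$manifest$samples$proz, c$manifest$samples$proz))
})

test_that("null effect sizes make case and control marginals indistinguishable", {
  # rank test on ~1000 draws per arm, repeated over 50 seeds; at alpha 0.01
  # at least 48 runs must be non-significant
  # one draw per subject so the rank test's independence assumption holds
  nonsig <- 0L
  for (s in 1:50) {
    cfg <- generator_config(n_control = 500, n_type1 = 500, n_type2 = 0,
                            type1_responder_fraction = 1,
                            type1_decay = list(amplitude = 0, tau = 1000),
                            visits_per_subject = 1, seed = 1000 + s)
    sf <- simulate_cohort(cfg)$manifest
    s2 <- merge(sf$samples, sf$subjects[c("subject_id", "group")],
                by = "subject_id")
    p <- stats::wilcox.test(s2$proz[s2$group == "case"],
                            s2$proz[s2$group == "control"],
                            exact = FALSE)$p.value
    if (p > 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 48L)
})

test_that("responder mean near diagnosis matches the closed-form anchor", {
  cfg <- generator_config()
  # the multiplier is anchored exactly: 1 - A at diagnosis, 1 at changepoint
  expect_equal(serodetect:::.type1_multiplier(0, 0.9, 1000, 420), 0.1)
  expect_equal(serodetect:::.type1_multiplier(420, 0.9, 1000, 420), 1)
  # Monte-Carlo check of the generated levels against the closed form:
  # geometric mean of responder samples in a narrow window near diagnosis
  big <- generator_config(n_control = 0, n_type1 = 20000, n_type2 = 0,
                          type1_responder_fraction = 1,
                          visits_per_subject = 1, seed = 9)
  s <- simulate_cohort(big)$manifest$samples
  win <- s$days_to_diagnosis >= 30 & s$days_to_diagnosis <= 60
  expect_gt(sum(win), 1000)
  expected <- exp(big$proz_log_mean) *
    mean(serodetect:::.type1_multiplier(s$days_to_diagnosis[win], 0.9, 1000, 420))
  observed <- exp(mean(log(s$proz[win])))
  expect_equal(observed, expected, tolerance = 0.03)
})

test_that("every case subject has a draw under 14 months pre-diagnosis", {
  m <- simulate_cohort(generator_config(seed = 5))$manifest
  cases <- m$subjects$subject_id[m$subjects$group == "case"]
  last_draw <- vapply(cases, function(sid) {
    min(m$samples$days_to_diagnosis[m$samples$subject_id == sid])
  }, numeric(1))
  expect_true(all(last_draw < 426))
})

test_that("control marginals are time-stationary across the horizon", {
  # early-half vs late-half rank test non-significant in >= 95 of 100 runs
  nonsig <- 0L
  for (s in 1:100) {
    cfg <- generator_config(n_control = 40, n_type1 = 0, n_type2 = 0,
                            seed = 2000 + s)
    smp <- simulate_cohort(cfg)$manifest$samples
    cut <- stats::median(smp$days_to_diagnosis)
    p <- stats::wilcox.test(smp$proz[smp$days_to_diagnosis <= cut],
                            smp$proz[smp$days_to_diagnosis > cut],
                            exact = FALSE)$p.value
    if (p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 95L)
})

test_that("the decay model recovers responder amplitude and tau from generated data", {
  # post-changepoint segment, large responder set, low noise: the generator
  # coincides with the c - A*exp(-d/tau) family there
  cfg <- generator_config(n_control = 0, n_type1 = 2000, n_type2 = 0,
                          type1_responder_fraction = 1,
                          proz_sigma_b = 0.05, proz_sigma_w = 0.05,
                          proz_sigma_rep = 0.01, seed = 11)
  s <- simulate_cohort(cfg)$manifest$samples
  seg <- s[s$days_to_diagnosis <= cfg$type1_changepoint, ]
  fit <- fit_decay(seg$days_to_diagnosis, seg$proz)
  k0 <- exp(-cfg$type1_changepoint / cfg$type1_decay$tau)
  C <- exp(cfg$proz_log_mean +
             (cfg$proz_sigma_b^2 + cfg$proz_sigma_w^2 + cfg$proz_sigma_rep^2) / 2)
  amp_frac <- fit$A * (1 - k0) / C
  expect_lt(abs(fit$tau - cfg$type1_decay$tau) / cfg$type1_decay$tau, 0.15)
  expect_lt(abs(amp_frac - cfg$type1_decay$amplitude) /
              cfg$type1_decay$amplitude, 0.15)
})

test_that("simulated peptide tables honour the pooling design", {
  # zero noise, zero effects: every cross-channel ratio is exactly 1
  sim <- simulate_peptide_table(5, 3, noise_sd = 0, seed = 1)
  chans <- itraq_design()$channels
  for (ch in chans[-1]) {
    expect_equal(sim$table[[ch]], sim$table[[chans[1]]])
  }
  expect_true(all(c("119", "121") %in% names(sim$table)))

  # a log2 effect of 1 doubles the measured protein ratio up to noise
  sim2 <- simulate_peptide_table(40, 4, effects = c(1, rep(0, 39)),
                                 noise_sd = 0.05, seed = 2)
  r <- protein_log_ratios(sim2$table, c("113", "117"))
  expect_equal(r$log2_ratio[r$protein_id == "P0001"], 1, tolerance = 0.15)
  expect_equal(mean(r$log2_ratio[r$protein_id != "P0001"]), 0,
               tolerance = 0.05)

  expect_error(simulate_peptide_table(5, 1), "2 peptides")
})

test_that("discovery pools cover six groups and pool means are exact", {
  pools <- select_discovery_pools(fixture_cohort())
  expect_setequal(unique(pools$members$pool),
                  c("control_early", "control_far", "type1_early",
                    "type1_far", "type2_early", "type2_far"))
  expect_identical(nrow(pools$pooled), 6L)
  expect_identical(nrow(pools$exclusions), 0L)
  # pooled value equals brute-force mean over members
  for (p in pools$pooled$pool) {
    expect_equal(pools$pooled$proz[pools$pooled$pool == p],
                 mean(pools$members$proz[pools$members$pool == p]))
  }

  # single subject with both windows: pools of size one, pooled value is
  # the sample value
  m <- tiny_manifest()
  one <- cohort_manifest(m$subjects[1, , drop = FALSE],
                         m$samples[m$samples$subject_id == "C1", ])
  p1 <- select_discovery_pools(one)
  expect_identical(p1$pooled$n, c(1L, 1L))
  expect_equal(sort(p1$pooled$proz), sort(p1$members$proz))
})
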