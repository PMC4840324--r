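test_that("single-marker AUC matches the pairwise brute-force oracle", {
  # perfectly separated values
  perf <- single_marker_roc(c(1, 2, 3, 10, 11, 12),
                            c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(perf$auc, 1)

  # brute force over all case-control pairs with ties counted half
  set.seed(7)
  vals <- sample(1:8, 30, replace = TRUE)   # many ties
  lab <- stats::runif(30) < 0.4
  r <- single_marker_roc(vals, lab)
  pairs <- outer(vals[lab], vals[!lab],
                 function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(r$auc, mean(pairs))

  # lower_is_case flips the orientation
  r_low <- single_marker_roc(vals, lab, orientation = "lower_is_case")
  pairs_low <- outer(vals[lab], vals[!lab],
                     function(a, b) (a < b) + 0.5 * (a == b))
  expect_equal(r_low$auc, mean(pairs_low))

  expect_error(single_marker_roc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("the ROC curve is monotone and its trapezoid area equals the rank AUC", {
  set.seed(8)
  for (i in 1:10) {
    vals <- c(stats::rnorm(40, 1), sample(1:4, 20, replace = TRUE))
    lab <- c(stats::runif(40) < 0.5, rep(TRUE, 10), rep(FALSE, 10))
    r <- single_marker_roc(vals, lab)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(utils::tail(r$curve$tpr, 1), 1)
    expect_equal(trapezoid_auc(r$curve), r$auc, tolerance = 1e-9)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  vals <- stats::rlnorm(200, 3, 1)
  lab <- stats::runif(200) < 0.5
  base <- single_marker_roc(vals, lab)$auc
  expect_equal(single_marker_roc(log(vals), lab)$auc, base)
  expect_equal(single_marker_roc(vals^3, lab)$auc, base)
  expect_equal(single_marker_roc(1000 * vals + 7, lab)$auc, base)
})

test_that("uninformative labels give AUC near one half", {
  set.seed(10)
  vals <- stats::rnorm(4000)
  lab <- stats::runif(4000) < 0.5
  expect_equal(single_marker_roc(vals, lab)$auc, 0.5, tolerance = 0.05)
})

test_that("rank AUC agrees with an independent ROC implementation", {
  set.seed(11)
  vals <- c(stats::rnorm(60, 1), stats::rnorm(60, 0))
  lab <- rep(c(1, 0), each = 60)
  ours <- single_marker_roc(vals, lab)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(lab, vals, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("the combined panel exploits complementary markers", {
  # two independent markers of similar single AUC: the SVM combination
  # should beat each single marker in most replicates
  wins <- 0L
  for (s in 1:20) {
    set.seed(400 + s)
    nsub <- 150
    nv <- 3
    subj <- rep(sprintf("s%03d", 1:nsub), each = nv)
    case <- rep(c(rep(TRUE, nsub / 2), rep(FALSE, nsub / 2)), each = nv)
    sig1 <- rep(stats::rnorm(nsub, ifelse(case[seq(1, nsub * nv, nv)], 1, 0)), each = nv)
    sig2 <- rep(stats::rnorm(nsub, ifelse(case[seq(1, nsub * nv, nv)], 1, 0)), each = nv)
    m1 <- 10^(sig1 + stats::rnorm(nsub * nv, 0, 0.3))
    m2 <- 10^(sig2 + stats::rnorm(nsub * nv, 0, 0.3))
    a1 <- single_marker_roc(m1, case)$auc
    a2 <- single_marker_roc(m2, case)$auc
    ac <- combined_roc(m1, m2, case, subj, seed = s)$auc
    if (ac > a1 && ac > a2) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})

test_that("adding a pure-noise marker leaves the combined AUC near the single one", {
  set.seed(12)
  nsub <- 80
  nv <- 3
  subj <- rep(sprintf("s%02d", 1:nsub), each = nv)
  case <- rep(c(rep(TRUE, nsub / 2), rep(FALSE, nsub / 2)), each = nv)
  sig <- rep(stats::rnorm(nsub, ifelse(case[seq(1, nsub * nv, nv)], 1.2, 0)),
             each = nv)
  informative <- 10^(sig + stats::rnorm(nsub * nv, 0, 0.3))
  noise <- 10^stats::rnorm(nsub * nv, 0, 0.5)
  single <- single_marker_roc(informative, case)$auc
  combined <- combined_roc(informative, noise, case, subj, seed = 1)$auc
  expect_equal(combined, single, tolerance = 0.08)
})

test_that("fold assignment never splits a subject across train and test", {
  set.seed(13)
  nsub <- 30
  subj <- rep(sprintf("s%02d", 1:nsub), each = 4)
  case <- rep(stats::runif(nsub) < 0.5, each = 4)
  if (length(unique(case)) < 2) case[1:40] <- rep(c(TRUE, FALSE), each = 20)
  r <- combined_roc(stats::rlnorm(nsub * 4), stats::rlnorm(nsub * 4),
                    case, subj, seed = 2)
  folds_per_subject <- tapply(r$fold, subj, function(f) length(unique(f)))
  expect_true(all(folds_per_subject == 1L))
})

test_that("the AUC difference test is exact for identical scores and powered for synergy", {
  set.seed(14)
  vals <- stats::rnorm(120)
  lab <- rep(c(TRUE, FALSE), 60)
  subj <- rep(sprintf("s%02d", 1:30), each = 4)
  r1 <- single_marker_roc(vals, lab)
  expect_equal(auc_difference_test(r1, r1, subj, n_boot = 200)$p_value, 1)

  # unpaired inputs are rejected
  r2 <- single_marker_roc(vals[1:60], lab[1:60])
  expect_error(auc_difference_test(r1, r2, subj), "paired")

  # strong synergy: combined beats one marker with p < 0.01 in most seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(500 + s)
    nsub <- 150
    nv <- 3
    subj <- rep(sprintf("s%03d", 1:nsub), each = nv)
    case <- rep(c(rep(TRUE, nsub / 2), rep(FALSE, nsub / 2)), each = nv)
    strong <- rep(stats::rnorm(nsub, ifelse(case[seq(1, nsub * nv, nv)], 1.3, 0)),
                  each = nv)
    weak <- rep(stats::rnorm(nsub, ifelse(case[seq(1, nsub * nv, nv)], 0.1, 0)),
                each = nv)
    m_strong <- 10^(strong + stats::rnorm(nsub * nv, 0, 0.2))
    m_weak <- 10^(weak + stats::rnorm(nsub * nv, 0, 0.2))
    rc <- combined_roc(m_strong, m_weak, case, subj, seed = s)
    rw <- single_marker_roc(m_weak, case)
    p <- auc_difference_test(rc, rw, subj, n_boot = 1000, seed = s)$p_value
    if (p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
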