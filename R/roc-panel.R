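#' @title ROC analysis of single markers and the combined panel
#' @name roc_panel
#' @description
#' Sample-level ROC analysis: AUC by the rank (Mann-Whitney) statistic with
#' ties counted half, the full ROC curve from a threshold sweep, an
#' SVM-combined two-marker panel scored out-of-fold with subject-aware
#' cross-validation, and a paired subject-level bootstrap test for the
#' difference between two AUCs on the same samples.
NULL

# Rank-statistic AUC with ties counted one half; equals the probability
# that a random case scores above a random control.
.rank_auc <- function(scores, is_case) {
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.roc_curve <- function(scores, is_case) {
  # sweep thresholds over observed scores, descending; tied scores move
  # together so tied case/control groups trace a diagonal segment
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- is_case[o]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  last <- !duplicated(s, fromLast = TRUE)   # last index of each tied block
  data.frame(fpr = c(0, fp[last] / sum(!is_case)),
             tpr = c(0, tp[last] / sum(is_case)))
}

#' Single-marker ROC
#'
#' @param values marker levels, one per sample.
#' @param labels logical (or coercible) case indicator per sample.
#' @param orientation `"higher_is_case"` (default) or `"lower_is_case"`
#'   (e.g. a marker that falls pre-diagnosis).
#' @param marker_set label carried in the result.
#' @return list of class `roc_result`: `marker_set`, `auc`, `curve`
#'   (data frame `fpr`, `tpr` from (0,0) to (1,1)), `n_case`, `n_control`,
#'   `orientation`.  The trapezoidal area under `curve` equals `auc` to
#'   numerical precision.
#' @export
single_marker_roc <- function(values, labels,
                              orientation = c("higher_is_case",
                                              "lower_is_case"),
                              marker_set = "marker") {
  orientation <- match.arg(orientation)
  is_case <- as.logical(labels)
  ok <- is.finite(values) & !is.na(is_case)
  values <- values[ok]
  is_case <- is_case[ok]
  scores <- if (orientation == "lower_is_case") -values else values
  structure(list(marker_set = marker_set,
                 auc = .rank_auc(scores, is_case),
                 curve = .roc_curve(scores, is_case),
                 scores = scores, is_case = is_case,
                 n_case = sum(is_case), n_control = sum(!is_case),
                 orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC [%s]: AUC = %.3f (%d case vs %d control samples)\n",
              x$marker_set, x$auc, x$n_case, x$n_control))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve data frame with `fpr`, `tpr` in non-decreasing order.
#' @return area under the curve.
#' @export
trapezoid_auc <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                           utils::tail(curve$tpr, -1)) / 2)
}

#' Combined two-marker ROC via linear SVM with subject-aware folds
#'
#' Both markers are `log10(x + 1)` transformed and standardised with
#' training-fold parameters; a linear support-vector classifier (cost
#' fixed, default 1) is trained per fold and its decision scores on the
#' held-out fold are pooled into one ROC.  Folds are assigned by subject so
#' no subject's samples straddle train and test.
#'
#' @param ca125,proz the two marker levels, one per sample.
#' @param labels case indicator per sample.
#' @param subject_ids subject of each sample (fold unit).
#' @param cv_folds number of folds, default 5.
#' @param cost SVM cost parameter.
#' @param seed integer seed for the fold assignment.
#' @return `roc_result` with `marker_set = "combined"` and the pooled
#'   out-of-fold `scores`.
#' @export
combined_roc <- function(ca125, proz, labels, subject_ids, cv_folds = 5,
                         cost = 1, seed = 1L) {
  is_case <- as.logical(labels)
  stopifnot(length(ca125) == length(proz),
            length(proz) == length(is_case),
            length(is_case) == length(subject_ids))
  if (sum(is_case) < 10L || sum(!is_case) < 10L) {
    stop("at least 10 samples per class are required")
  }
  x <- cbind(ca125 = log10(ca125 + 1), proz = log10(proz + 1))
  subjects <- unique(subject_ids)
  set.seed(seed)
  for (attempt in 1:25) {
    fold_of_subject <- sample(rep_len(seq_len(cv_folds), length(subjects)))
    fold <- fold_of_subject[match(subject_ids, subjects)]
    degenerate <- any(vapply(seq_len(cv_folds), function(f) {
      length(unique(is_case[fold != f])) < 2L
    }, logical(1)))
    if (!degenerate) break
    warning("degenerate fold (one class absent in training); refolding")
  }
  if (degenerate) stop("could not build non-degenerate subject folds")
  scores <- numeric(length(is_case))
  y <- factor(ifelse(is_case, "case", "control"),
              levels = c("case", "control"))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f
    te <- fold == f
    if (!any(te)) next
    mu <- colMeans(x[tr, , drop = FALSE])
    sdv <- pmax(apply(x[tr, , drop = FALSE], 2, stats::sd), 1e-12)
    xtr <- scale(x[tr, , drop = FALSE], center = mu, scale = sdv)
    xte <- scale(x[te, , drop = FALSE], center = mu, scale = sdv)
    fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = cost,
                      scale = FALSE)
    dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
               "decision.values")
    # e1071 orients decision values toward the first factor level of the
    # training data; force "case-positive" orientation explicitly
    sgn <- if (colnames(dv)[1L] == "case/control") 1 else -1
    scores[te] <- sgn * dv[, 1L]
  }
  structure(list(marker_set = "combined",
                 auc = .rank_auc(scores, is_case),
                 curve = .roc_curve(scores, is_case),
                 scores = scores, is_case = is_case,
                 n_case = sum(is_case), n_control = sum(!is_case),
                 orientation = "higher_is_case",
                 cv_folds = cv_folds, cost = cost, fold = fold),
            class = "roc_result")
}

#' Paired bootstrap test for an AUC difference
#'
#' Both score sets must be defined on the same samples.  Subjects are
#' resampled with replacement; both AUCs are recomputed on each resample
#' and the bootstrap distribution of the difference, centred at zero, gives
#' a two-sided add-one-corrected p-value for the observed difference.
#'
#' @param roc_a,roc_b `roc_result` objects carrying `scores` and `is_case`
#'   over the same samples (checked by length and class composition).
#' @param subject_ids subject of each sample (resampling unit).
#' @param n_boot bootstrap replicates, default 2000.
#' @param seed integer seed.
#' @return list of class `auc_difference`: `delta` (AUC a minus AUC b),
#'   `p_value`, `ci` (percentile 95% interval of the bootstrap
#'   differences), `n_boot`.
#' @export
auc_difference_test <- function(roc_a, roc_b, subject_ids, n_boot = 2000,
                                seed = 1L) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (length(roc_a$scores) != length(roc_b$scores) ||
      !identical(roc_a$is_case, roc_b$is_case)) {
    stop("the two score sets must be paired over the same samples")
  }
  stopifnot(length(subject_ids) == length(roc_a$scores))
  is_case <- roc_a$is_case
  delta_obs <- roc_a$auc - roc_b$auc
  by_subj <- split(seq_along(subject_ids), subject_ids)
  n_subj <- length(by_subj)
  set.seed(seed)
  delta_boot <- numeric(n_boot)
  b <- 1L
  while (b <= n_boot) {
    pick <- sample.int(n_subj, n_subj, replace = TRUE)
    idx <- unlist(by_subj[pick], use.names = FALSE)
    if (!any(is_case[idx]) || all(is_case[idx])) next  # need both classes
    delta_boot[b] <- .rank_auc(roc_a$scores[idx], is_case[idx]) -
      .rank_auc(roc_b$scores[idx], is_case[idx])
    b <- b + 1L
  }
  null_stats <- delta_boot - delta_obs   # bootstrap null centred at zero
  p <- (1 + sum(abs(null_stats) >= abs(delta_obs))) / (n_boot + 1)
  structure(list(delta = delta_obs, p_value = p,
                 ci = stats::quantile(delta_boot, c(0.025, 0.975),
                                      names = FALSE),
                 n_boot = n_boot),
            class = "auc_difference")
}

#' @export
print.auc_difference <- function(x, ...) {
  cat(sprintf("AUC difference = %.4f (95%% CI %.4f to %.4f), bootstrap p = %.4g\n",
              x$delta, x$ci[1L], x$ci[2L], x$p_value))
  invisible(x)
}

#' Bootstrap confidence interval for a single AUC
#'
#' Subject-level percentile bootstrap.
#'
#' @param roc a `roc_result`.
#' @param subject_ids subject of each sample.
#' @param n_boot replicates, default 2000.
#' @param seed integer seed.
#' @return length-2 numeric, the 2.5% and 97.5% percentile bounds.
#' @export
auc_ci <- function(roc, subject_ids, n_boot = 2000, seed = 1L) {
  stopifnot(inherits(roc, "roc_result"))
  by_subj <- split(seq_along(subject_ids), subject_ids)
  n_subj <- length(by_subj)
  set.seed(seed)
  aucs <- numeric(n_boot)
  b <- 1L
  while (b <= n_boot) {
    pick <- sample.int(n_subj, n_subj, replace = TRUE)
    idx <- unlist(by_subj[pick], use.names = FALSE)
    if (!any(roc$is_case[idx]) || all(roc$is_case[idx])) next
    aucs[b] <- .rank_auc(roc$scores[idx], roc$is_case[idx])
    b <- b + 1L
  }
  stats::quantile(aucs, c(0.025, 0.975), names = FALSE)
}
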