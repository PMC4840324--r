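#' @title Percentile-threshold case detection and lead-time analysis
#' @name threshold_detection
#' @description
#' Empirical detection rules on serial samples: the Protein Z thresholds
#' are the 1st and 99th percentiles of all control measurements (an
#' empirical ~1% false-positive rule in each direction), Type I cases are
#' detected when any sample falls strictly below the low threshold, Type II
#' cases when any sample rises strictly above the high one, and CA-125
#' detection uses the clinical referral cut-off of 35 U/ml (strictly
#' above).  Detection times are compared with each subject's first
#' ROCA-positive sample to give lead times.
NULL

#' Fit percentile detection thresholds on control samples
#'
#' Percentiles use linear interpolation between the closest order
#' statistics (R's default quantile type 7); the convention is recorded in
#' the output.  Thresholds must be fitted on control measurements only.
#'
#' @param control_proz control Protein Z measurements (sample means of
#'   replicates), ng/ml.  Fewer than 10 is an error; fewer than 100 draws a
#'   warning (the empirical 1st percentile is then poorly determined).
#' @param percentiles the low and high percentile, default `c(1, 99)`.
#' @param ca125_clinical clinical CA-125 referral threshold, U/ml.
#' @return list of class `threshold_set`: `proz_low`, `proz_high`,
#'   `ca125_clinical`, `percentiles`, `n_control`,
#'   `quantile_type = 7`.
#' @export
fit_thresholds <- function(control_proz, percentiles = c(1, 99),
                           ca125_clinical = 35) {
  control_proz <- control_proz[is.finite(control_proz)]
  if (length(control_proz) < 10L) {
    stop("at least 10 control measurements are required")
  }
  if (length(control_proz) < 100L) {
    warning("fewer than 100 control measurements: percentile thresholds are imprecise")
  }
  stopifnot(length(percentiles) == 2L, percentiles[1L] < percentiles[2L])
  qq <- stats::quantile(control_proz, percentiles / 100, type = 7,
                        names = FALSE)
  structure(list(proz_low = qq[1L], proz_high = qq[2L],
                 ca125_clinical = ca125_clinical,
                 percentiles = percentiles,
                 n_control = length(control_proz), quantile_type = 7L),
            class = "threshold_set")
}

#' @export
print.threshold_set <- function(x, ...) {
  cat(sprintf("thresholds: proz < %.4g or > %.4g ng/ml (%gth/%gth pctl of %d controls), ca125 > %g U/ml\n",
              x$proz_low, x$proz_high, x$percentiles[1L], x$percentiles[2L],
              x$n_control, x$ca125_clinical))
  invisible(x)
}

.first_crossing_days <- function(days, crossed) {
  if (!any(crossed)) return(NA_real_)
  max(days[crossed])          # earliest calendar time = largest days value
}

#' Detect case subjects by threshold crossing
#'
#' Type I cases (including borderline) are flagged when any sample mean
#' falls strictly below `proz_low`; Type II cases when any rises strictly
#' above `proz_high`.  CA-125 detection requires any sample strictly above
#' the clinical threshold.  `first_*_days` is the largest
#' `days_to_diagnosis` among crossing samples, i.e. the earliest crossing.
#' A subject's first ROCA-positive time is the largest days value whose
#' annotation is `intermediate` or `elevated`.
#'
#' @param m a `cohort_manifest`.
#' @param thresholds a [fit_thresholds()] result (fitted on controls only).
#' @return data frame, one row per case subject: `subject_id`,
#'   `cancer_type`, `detected_by_proz`, `direction`, `first_detection_days`,
#'   `detected_by_ca125`, `ca125_first_days`, `roca_first_positive_days`,
#'   `lead_vs_roca` (positive = marker earlier than ROCA), `n_samples`.
#' @export
detect_cases <- function(m, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  validate_manifest(m)
  cases <- m$subjects[m$subjects$group == "case", , drop = FALSE]
  unknown <- cases$subject_id[!cases$cancer_type %in% c("type1", "type2")]
  if (length(unknown) > 0L) {
    warning(sprintf("skipping subject(s) with unknown cancer type: %s",
                    paste(unknown, collapse = ", ")))
    cases <- cases[cases$cancer_type %in% c("type1", "type2"), , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    sid <- cases$subject_id[i]
    ctype <- cases$cancer_type[i]
    ss <- m$samples[m$samples$subject_id == sid, , drop = FALSE]
    if (ctype == "type1") {
      crossed <- !is.na(ss$proz) & ss$proz < thresholds$proz_low
      direction <- "low"
    } else {
      crossed <- !is.na(ss$proz) & ss$proz > thresholds$proz_high
      direction <- "high"
    }
    ca_crossed <- !is.na(ss$ca125) & ss$ca125 > thresholds$ca125_clinical
    roca_pos <- !is.na(ss$roca_class) &
      ss$roca_class %in% c("intermediate", "elevated")
    first_proz <- .first_crossing_days(ss$days_to_diagnosis, crossed)
    first_ca <- .first_crossing_days(ss$days_to_diagnosis, ca_crossed)
    first_roca <- .first_crossing_days(ss$days_to_diagnosis, roca_pos)
    data.frame(subject_id = sid, cancer_type = ctype,
               detected_by_proz = any(crossed),
               direction = if (any(crossed)) direction else NA_character_,
               first_detection_days = first_proz,
               detected_by_ca125 = any(ca_crossed),
               ca125_first_days = first_ca,
               roca_first_positive_days = first_roca,
               lead_vs_roca = first_proz - first_roca,
               n_samples = nrow(ss),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), cancer_type = character(),
               detected_by_proz = logical(), direction = character(),
               first_detection_days = numeric(),
               detected_by_ca125 = logical(), ca125_first_days = numeric(),
               roca_first_positive_days = numeric(),
               lead_vs_roca = numeric(), n_samples = integer())
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  out
}

#' Lead-time summary of detection results
#'
#' @param results a [detect_cases()] data frame.
#' @return list: `per_type` (per cancer type: counts detected by the marker
#'   and by CA-125, the cross-classification `proz_only` / `ca125_only` /
#'   `both` / `neither`, median first detection days among detected, and
#'   median lead versus ROCA among detected) and `per_subject` (the input
#'   with lead columns).
#' @export
leadtime_report <- function(results) {
  per_type <- lapply(split(results, results$cancer_type), function(df) {
    det <- df$detected_by_proz
    ca <- df$detected_by_ca125
    data.frame(cancer_type = df$cancer_type[1L],
               n_cases = nrow(df),
               n_detected_proz = sum(det),
               n_detected_ca125 = sum(ca),
               proz_only = sum(det & !ca),
               ca125_only = sum(!det & ca),
               both = sum(det & ca),
               neither = sum(!det & !ca),
               median_first_detection_days =
                 stats::median(df$first_detection_days[det]),
               median_lead_vs_roca =
                 stats::median(df$lead_vs_roca[det], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  per_type <- do.call(rbind, per_type)
  rownames(per_type) <- NULL
  list(per_type = per_type, per_subject = results)
}

#' Cross-type threshold breach matrix
#'
#' Counts how often samples of each case type breach the threshold meant
#' for the *other* type (and their own), quantifying the mutual
#' exclusivity of a low-direction Type I signal and a high-direction
#' Type II signal.
#'
#' @param m a `cohort_manifest`.
#' @param thresholds a [fit_thresholds()] result.
#' @return data frame with one row per cancer type and columns
#'   `n_samples`, `n_below_low`, `frac_below_low`, `n_above_high`,
#'   `frac_above_high`.
#' @export
exclusivity_matrix <- function(m, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  validate_manifest(m)
  s <- merge(m$samples, m$subjects[c("subject_id", "cancer_type")],
             by = "subject_id")
  out <- lapply(c("type1", "type2"), function(ct) {
    x <- s$proz[s$cancer_type == ct]
    x <- x[!is.na(x)]
    n <- length(x)
    below <- sum(x < thresholds$proz_low)
    above <- sum(x > thresholds$proz_high)
    data.frame(cancer_type = ct, n_samples = n,
               n_below_low = below,
               frac_below_low = if (n > 0) below / n else NA_real_,
               n_above_high = above,
               frac_above_high = if (n > 0) above / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
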