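#' @title Pooled isobaric-tag differential-expression filter
#' @name itraq_discovery
#' @description
#' Discovery-stage significance filtering of pooled reporter-ion data.
#' A protein's relative quantification uses at least two peptides; the
#' duplicate reference channels (the same pooled sample labelled twice)
#' yield an empirical 95% interval of purely technical log-ratio variation,
#' and a protein is called significant only when its ratio falls outside
#' that interval, it was identified from at least two peptides, and its
#' upstream identification p-value is below alpha.  Ratios are handled on
#' the log2 scale throughout.
NULL

#' Per-protein log2 ratios from a peptide table
#'
#' Computes per-peptide log2 ratios between two channels and aggregates them
#' per protein by the median (a robust choice; the aggregator is not fixed
#' by the filtering rule).  Proteins with fewer than two usable peptides are
#' excluded from the output and listed in the exclusion report.  Peptides
#' with non-positive intensity in either channel are dropped with a count
#' of warnings.
#'
#' @param table peptide data frame: `protein_id`, `peptide_id`, one
#'   intensity column per channel, optionally `identification_p`.
#' @param contrast length-2 character vector `c(numerator, denominator)`.
#' @return data frame (`protein_id`, `n_peptides`, `log2_ratio`,
#'   `identification_p`) with attributes `excluded` (protein ids with < 2
#'   usable peptides) and `n_dropped_peptides`.
#' @export
protein_log_ratios <- function(table, contrast) {
  stopifnot(length(contrast) == 2L)
  missing_ch <- setdiff(contrast, names(table))
  if (length(missing_ch) > 0L) {
    stop(sprintf("channel(s) not in table: %s",
                 paste(missing_ch, collapse = ", ")))
  }
  num <- table[[contrast[1L]]]
  den <- table[[contrast[2L]]]
  usable <- is.finite(num) & is.finite(den) & num > 0 & den > 0
  n_dropped <- sum(!usable)
  if (n_dropped > 0L) {
    warning(sprintf("%d peptide(s) dropped for non-positive or missing intensity",
                    n_dropped))
  }
  tab <- table[usable, , drop = FALSE]
  ratio <- log2(tab[[contrast[1L]]]) - log2(tab[[contrast[2L]]])
  split_ratio <- split(ratio, tab$protein_id)
  n_pep <- vapply(split_ratio, length, integer(1))
  med <- vapply(split_ratio, stats::median, numeric(1))
  id_p <- if ("identification_p" %in% names(tab)) {
    vapply(split(tab$identification_p, tab$protein_id),
           function(x) x[1L], numeric(1))
  } else {
    rep(NA_real_, length(split_ratio))
  }
  out <- data.frame(protein_id = names(split_ratio),
                    n_peptides = unname(n_pep),
                    log2_ratio = unname(med),
                    identification_p = unname(id_p),
                    stringsAsFactors = FALSE)
  keep <- out$n_peptides >= 2L
  excluded <- out$protein_id[!keep]
  # proteins whose peptides were all dropped also count as excluded
  excluded <- union(excluded, setdiff(unique(table$protein_id),
                                      out$protein_id))
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "excluded") <- sort(excluded)
  attr(res, "n_dropped_peptides") <- n_dropped
  res
}

#' Technical-variation interval from duplicate reference channels
#'
#' The two reference channels label the same pool, so their protein-level
#' log2 ratios measure technical variation only.  The interval is
#' `mean +/- z * sd` of those ratios with `z` the two-sided normal quantile
#' for the requested coverage (1.96 at 0.95).  A percentile-based interval
#' is available as an alternative.
#'
#' @param table peptide table (see [protein_log_ratios()]).
#' @param duplicate_pair the two duplicate reference channels.
#' @param coverage interval coverage, default 0.95.
#' @param method `"normal"` (default) or `"percentile"`.
#' @return list of class `technical_interval`: `lower`, `upper`,
#'   `n_proteins_used`, `coverage`, `method`, `scale = "log2"`.
#' @export
technical_interval <- function(table, duplicate_pair, coverage = 0.95,
                               method = c("normal", "percentile")) {
  method <- match.arg(method)
  ratios <- protein_log_ratios(table, duplicate_pair)
  if (nrow(ratios) < 3L) {
    stop("fewer than 3 proteins with >= 2 peptides: insufficient data for a technical interval")
  }
  x <- ratios$log2_ratio
  if (method == "normal") {
    z <- stats::qnorm(1 - (1 - coverage) / 2)
    lower <- mean(x) - z * stats::sd(x)
    upper <- mean(x) + z * stats::sd(x)
  } else {
    qq <- stats::quantile(x, c((1 - coverage) / 2, 1 - (1 - coverage) / 2),
                          type = 7, names = FALSE)
    lower <- qq[1L]
    upper <- qq[2L]
  }
  structure(list(lower = lower, upper = upper,
                 n_proteins_used = nrow(ratios), coverage = coverage,
                 method = method, scale = "log2"),
            class = "technical_interval")
}

#' @export
print.technical_interval <- function(x, ...) {
  cat(sprintf("technical interval (%s, %.0f%% coverage, log2): [%.4f, %.4f] from %d proteins\n",
              x$method, 100 * x$coverage, x$lower, x$upper,
              x$n_proteins_used))
  invisible(x)
}

#' Flag significantly changed proteins
#'
#' A protein is flagged if and only if all three criteria hold: upstream
#' identification p-value below `alpha`, at least two peptides, and log2
#' ratio outside the technical interval.
#'
#' @param ratios output of [protein_log_ratios()].
#' @param interval a [technical_interval()].
#' @param alpha identification significance threshold, default 0.05.
#' @return data frame (`protein_id`, `n_peptides`, `log2_ratio`,
#'   `identification_p`, `flagged`, `reason`), where `reason` explains a
#'   negative call.
#' @export
flag_significant <- function(ratios, interval, alpha = 0.05) {
  stopifnot(inherits(interval, "technical_interval"))
  p_ok <- !is.na(ratios$identification_p) & ratios$identification_p < alpha
  pep_ok <- ratios$n_peptides >= 2L
  outside <- ratios$log2_ratio < interval$lower |
    ratios$log2_ratio > interval$upper
  flagged <- p_ok & pep_ok & outside
  reason <- rep("significant", nrow(ratios))
  reason[!outside] <- "within technical interval"
  reason[!p_ok] <- "identification p >= alpha"
  reason[!pep_ok] <- "fewer than 2 peptides"
  out <- ratios
  out$flagged <- flagged
  out$reason <- reason
  attr(out, "interval") <- interval
  attr(out, "alpha") <- alpha
  out
}
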