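#' @title Targeted panel verification with volcano classification
#' @name swath_panel
#' @description
#' Verification stage for a targeted protein panel quantified across
#' replicate runs of pooled samples (the data-independent-acquisition
#' design runs each pool in triplicate).  Protein abundance is the mean of
#' per-peptide log2 intensities over at least two peptides.  Each stratum
#' (cancer type x time window) is compared case-vs-control with a
#' two-sample t statistic on replicate runs, and proteins are volcano-
#' classified: `up`/`down` require at least a twofold change and
#' p below alpha.  The panel discriminators are the proteins significant in
#' every stratum.
NULL

#' Protein-by-run abundance matrix from a peptide table
#'
#' Abundance is the mean over a protein's peptides of log2 intensity,
#' computed per run.  Proteins with fewer than two peptides are excluded
#' (the protein estimation rule) and reported in the `excluded` attribute.
#'
#' @param table data frame: `protein_id`, `peptide_id`, one intensity
#'   column per run.
#' @param runs run column names; defaults to every column except
#'   `protein_id`, `peptide_id` and `identification_p`.
#' @return numeric matrix (proteins x runs) of log2 abundances, with
#'   attribute `excluded`.
#' @export
protein_abundance <- function(table, runs = NULL) {
  if (is.null(runs)) {
    runs <- setdiff(names(table), c("protein_id", "peptide_id",
                                    "identification_p"))
  }
  stopifnot(length(runs) >= 1L, all(runs %in% names(table)))
  vals <- as.matrix(table[runs])
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("intensities must be positive and finite")
  }
  logv <- log2(vals)
  counts <- table(table$protein_id)
  keep <- names(counts)[counts >= 2L]
  excluded <- sort(names(counts)[counts < 2L])
  idx <- table$protein_id %in% keep
  ab <- rowsum(logv[idx, , drop = FALSE], table$protein_id[idx]) /
    as.vector(counts[sort(keep)])
  ab <- ab[sort(keep), , drop = FALSE]
  attr(ab, "excluded") <- excluded
  ab
}

.welch_t_p <- function(x, y) {
  # two-sample t on replicate runs; degenerate zero-variance cases resolved
  # to p = 1 (equal means) or p = 0 (different means, infinite t)
  vx <- stats::var(x)
  vy <- stats::var(y)
  if ((is.na(vx) || vx == 0) && (is.na(vy) || vy == 0)) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  stats::t.test(x, y)$p.value
}

#' Case-versus-control comparison for one stratum
#'
#' @param case_runs,control_runs protein x run log2-abundance matrices (as
#'   from [protein_abundance()]) with identical row sets; at least two
#'   replicate runs per side.
#' @param stratum label carried into the output (e.g. `"type1_early"`).
#' @param alpha significance level for volcano classification.
#' @param fold fold-change threshold; the default 2 encodes the "at least
#'   twofold" rule, i.e. |log2 fc| >= 1.
#' @return data frame (`protein_id`, `stratum`, `log2_fc`, `p_value`,
#'   `volcano_class`), `log2_fc` reported case minus control.
#' @export
compare_stratum <- function(case_runs, control_runs, stratum = "stratum",
                            alpha = 0.05, fold = 2) {
  stopifnot(ncol(case_runs) >= 2L, ncol(control_runs) >= 2L)
  common <- intersect(rownames(case_runs), rownames(control_runs))
  if (length(common) == 0L) stop("no proteins in common between the two sides")
  case_runs <- case_runs[common, , drop = FALSE]
  control_runs <- control_runs[common, , drop = FALSE]
  log2_fc <- rowMeans(case_runs) - rowMeans(control_runs)
  p <- vapply(seq_along(common), function(i) {
    .welch_t_p(case_runs[i, ], control_runs[i, ])
  }, numeric(1))
  lfc_cut <- log2(fold)
  cls <- rep("ns", length(common))
  cls[log2_fc >= lfc_cut & p < alpha] <- "up"
  cls[log2_fc <= -lfc_cut & p < alpha] <- "down"
  data.frame(protein_id = common, stratum = stratum, log2_fc = log2_fc,
             p_value = p, volcano_class = cls,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proteins discriminating in every stratum
#'
#' @param comparisons list of [compare_stratum()] outputs (one per stratum)
#'   or a single row-bound data frame of them.
#' @return character vector of protein ids whose volcano class is not `ns`
#'   in every stratum in which they appear, restricted to proteins present
#'   in all strata.
#' @export
all_strata_discriminators <- function(comparisons) {
  if (is.data.frame(comparisons)) {
    comp <- comparisons
  } else {
    comp <- do.call(rbind, comparisons)
  }
  n_strata <- length(unique(comp$stratum))
  by_prot <- split(comp, comp$protein_id)
  hits <- vapply(by_prot, function(df) {
    nrow(df) == n_strata && all(df$volcano_class != "ns")
  }, logical(1))
  sort(names(by_prot)[hits])
}
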