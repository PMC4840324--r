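#' @title Pipeline orchestration
#' @name cli_pipeline
#' @description
#' Stage functions wiring the whole evaluation end to end: cohort
#' simulation, pooled discovery filtering, panel verification, longitudinal
#' validation (trajectories, binned tests, threshold detection, ROC
#' analysis) and a single collected report.  Each stage reads its inputs
#' from, and writes its outputs under, one output directory; one integer
#' seed fans out to fixed per-stage sub-seeds so stages are independently
#' reproducible.  A thin command-line wrapper over these functions ships
#' in `inst/scripts/pipeline.R`.
NULL

#' Pipeline configuration
#'
#' All analysis constants live here with their study defaults: 60-week
#' bins over a 420-week horizon, 1st/99th percentile thresholds, the
#' 35 U/ml CA-125 clinical cut-off, the twofold volcano rule at alpha
#' 0.05, and the 95% technical-variation interval.
#'
#' @param path optional YAML file whose top-level keys override defaults.
#' @param seed master integer seed.
#' @param generator a [generator_config()]; defaults to the study-design
#'   defaults with the stage sub-seed.
#' @param constants named list of analysis constants (see Details).
#' @param n_boot bootstrap replicates for the model comparison and AUC
#'   difference tests.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, seed = 1L, generator = NULL,
                            constants = list(), n_boot = 2000) {
  defaults <- list(bin_weeks = 60, horizon_weeks = 420,
                   percentiles = c(1, 99), ca125_clinical = 35,
                   fold = 2, alpha = 0.05, coverage = 0.95,
                   span = 0.75,
                   discovery = list(n_proteins = 200, n_peptides = 3,
                                    n_spiked = 10, effect = 1.5,
                                    noise_sd = 0.2),
                   panel = list(n_proteins = 20, n_peptides = 3,
                                n_runs = 3, effect = 1.5, noise_sd = 0.15))
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$seed)) seed <- as.integer(y$seed)
    if (!is.null(y$n_boot)) n_boot <- as.integer(y$n_boot)
    if (!is.null(y$constants)) constants <- utils::modifyList(constants, y$constants)
    if (!is.null(y$generator) && is.null(generator)) {
      generator <- do.call(generator_config, y$generator)
    }
  }
  constants <- utils::modifyList(defaults, constants)
  if (is.null(generator)) {
    generator <- generator_config(seed = .stage_seed(seed, 1L))
  }
  structure(list(seed = as.integer(seed), generator = generator,
                 constants = constants, n_boot = n_boot),
            class = "pipeline_config")
}

# deterministic per-stage sub-seeds, kept within 32-bit integer range
.stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 7919 + stage * 104729) %% .Machine$integer.max)
}

.config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(utils::capture.output(utils::str(config)), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

.stage_provenance <- function(outdir, stage, config) {
  jsonlite::write_json(list(stage = stage,
                            config_digest = .config_digest(config),
                            seed = config$seed),
                       file.path(outdir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE)
}

.require_stage <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("missing input '%s': run the '%s' stage first",
                 path, stage))
  }
  path
}

#' Simulation stage: write a cohort and its ground truth
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory, created if needed.
#' @return the simulated manifest, invisibly.
#' @export
run_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config$generator)
  write_cohort(sim$manifest, file.path(outdir, "subjects.tsv"),
               file.path(outdir, "samples.tsv"))
  .write_table(sim$truth, file.path(outdir, "truth.tsv"), "tsv")
  yaml::write_yaml(unclass(config$generator),
                   file.path(outdir, "generator_config.yaml"))
  .stage_provenance(outdir, "simulate", config)
  invisible(sim$manifest)
}

#' Discovery stage: pooled isobaric-tag significance filter
#'
#' Simulates a peptide-level reporter table with a known spiked subset,
#' derives the duplicate-reference technical interval and writes the
#' per-protein flag table.
#'
#' @inheritParams run_simulate
#' @return the flag table, invisibly.
#' @export
run_discovery <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dc <- config$constants$discovery
  effects <- c(rep(dc$effect, ceiling(dc$n_spiked / 2)),
               rep(-dc$effect, floor(dc$n_spiked / 2)),
               rep(0, dc$n_proteins - dc$n_spiked))
  design <- itraq_design()
  sim <- simulate_peptide_table(dc$n_proteins, dc$n_peptides,
                                design = design, effects = effects,
                                noise_sd = dc$noise_sd,
                                seed = .stage_seed(config$seed, 2L))
  ratios <- protein_log_ratios(sim$table,
                               c(design$case[1L], design$control[1L]))
  interval <- technical_interval(sim$table, design$reference,
                                 coverage = config$constants$coverage)
  flags <- flag_significant(ratios, interval,
                            alpha = config$constants$alpha)
  .write_table(flags, file.path(outdir, "discovery_flags.tsv"), "tsv")
  .write_table(sim$truth, file.path(outdir, "discovery_truth.tsv"), "tsv")
  jsonlite::write_json(list(lower = interval$lower, upper = interval$upper,
                            coverage = interval$coverage,
                            scale = interval$scale,
                            n_proteins_used = interval$n_proteins_used),
                       file.path(outdir, "technical_interval.json"),
                       auto_unbox = TRUE, digits = NA)
  .stage_provenance(outdir, "discovery", config)
  invisible(flags)
}

#' Panel stage: per-stratum volcano verification
#'
#' Simulates replicate-run abundances for a small targeted panel in each
#' of the four strata (two cancer types x two time windows), with the
#' first protein shifted in every stratum, then classifies each stratum's
#' volcano and extracts the all-strata discriminators.
#'
#' @inheritParams run_simulate
#' @return list with `comparisons` and `discriminators`, invisibly.
#' @export
run_panel <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pc <- config$constants$panel
  strata <- c("type1_early", "type1_far", "type2_early", "type2_far")
  design <- itraq_design(
    case_channels = paste0("case_run", seq_len(pc$n_runs)),
    control_channels = paste0("control_run", seq_len(pc$n_runs)),
    reference_channels = c("ref_a", "ref_b"))
  comparisons <- list()
  for (i in seq_along(strata)) {
    # protein 1 is the panel marker: shifted in every stratum (down in the
    # type1 strata, up in type2, mirroring a marker that falls in indolent
    # and rises in aggressive disease); protein 2 shifts in early strata only
    eff <- rep(0, pc$n_proteins)
    eff[1L] <- if (grepl("^type1", strata[i])) -pc$effect else pc$effect
    if (grepl("early", strata[i])) eff[2L] <- pc$effect
    sim <- simulate_peptide_table(pc$n_proteins, pc$n_peptides,
                                  design = design, effects = eff,
                                  noise_sd = pc$noise_sd,
                                  seed = .stage_seed(config$seed, 10L + i))
    ab_case <- protein_abundance(sim$table, runs = design$case)
    ab_ctrl <- protein_abundance(sim$table, runs = design$control)
    comparisons[[i]] <- compare_stratum(ab_case, ab_ctrl,
                                        stratum = strata[i],
                                        alpha = config$constants$alpha,
                                        fold = config$constants$fold)
  }
  comp <- do.call(rbind, comparisons)
  disc <- all_strata_discriminators(comp)
  .write_table(comp, file.path(outdir, "panel_comparisons.tsv"), "tsv")
  writeLines(disc, file.path(outdir, "panel_discriminators.txt"))
  .stage_provenance(outdir, "panel", config)
  invisible(list(comparisons = comp, discriminators = disc))
}

.sample_frame <- function(m) {
  merge(m$samples, m$subjects[c("subject_id", "group", "cancer_type")],
        by = "subject_id")
}

#' Validation stage: trajectories, bins, detection and ROC
#'
#' Reads the cohort written by [run_simulate()] (or any cohort placed in
#' `outdir`) and runs the full longitudinal analysis for each cancer type.
#'
#' @inheritParams run_simulate
#' @return the validation summary list, invisibly.
#' @export
run_validate <- function(config, outdir) {
  cst <- config$constants
  m <- read_cohort(.require_stage(file.path(outdir, "subjects.tsv"), "simulate"),
                   .require_stage(file.path(outdir, "samples.tsv"), "simulate"))
  s <- .sample_frame(m)
  ctrl <- s[s$group == "control", ]
  thresholds <- fit_thresholds(ctrl$proz, percentiles = cst$percentiles,
                               ca125_clinical = cst$ca125_clinical)
  detection <- detect_cases(m, thresholds)
  lead <- leadtime_report(detection)
  excl <- exclusivity_matrix(m, thresholds)

  per_type <- list()
  roc_rows <- list()
  for (ct in c("type1", "type2")) {
    cs <- s[s$cancer_type == ct, ]
    if (nrow(cs) < 10L) next
    trend <- loess_trend(cs$days_to_diagnosis, cs$proz, span = cst$span)
    bp <- estimate_breakpoint(trend)
    cmp <- compare_models(cs$days_to_diagnosis, cs$proz, cs$subject_id,
                          n_boot = config$n_boot,
                          seed = .stage_seed(config$seed, 20L))
    bins <- binned_tests(cs$days_to_diagnosis, cs$proz, ctrl$proz,
                         bin_weeks = cst$bin_weeks,
                         horizon_weeks = cst$horizon_weeks)
    .write_table(bins, file.path(outdir, paste0("bins_", ct, ".tsv")), "tsv")
    .write_table(trend, file.path(outdir, paste0("trend_", ct, ".tsv")), "tsv")

    both <- rbind(cs, ctrl)
    lab <- both$cancer_type == ct
    orient <- if (ct == "type1") "lower_is_case" else "higher_is_case"
    roc_ca <- single_marker_roc(both$ca125, lab, "higher_is_case", "ca125")
    roc_pz <- single_marker_roc(both$proz, lab, orient, "proz")
    roc_cb <- combined_roc(both$ca125, both$proz, lab, both$subject_id,
                           seed = .stage_seed(config$seed, 30L))
    dtest <- auc_difference_test(roc_cb, roc_ca, both$subject_id,
                                 n_boot = config$n_boot,
                                 seed = .stage_seed(config$seed, 40L))
    roc_rows[[ct]] <- data.frame(cancer_type = ct,
                                 auc_ca125 = roc_ca$auc,
                                 auc_proz = roc_pz$auc,
                                 auc_combined = roc_cb$auc,
                                 p_combined_vs_ca125 = dtest$p_value)
    best_bin <- bins[which.min(bins$p_value), , drop = FALSE]
    per_type[[ct]] <- list(
      breakpoint_days = bp,
      model_comparison_p = cmp$p_value,
      decay_amplitude = cmp$fit_decay$A,
      decay_tau = cmp$fit_decay$tau,
      best_bin_index = if (nrow(best_bin)) best_bin$bin_index else NA,
      best_bin_p = if (nrow(best_bin)) best_bin$p_value else NA,
      auc = roc_rows[[ct]])
  }
  summary <- list(thresholds = list(proz_low = thresholds$proz_low,
                                    proz_high = thresholds$proz_high,
                                    ca125_clinical = thresholds$ca125_clinical),
                  detection = lead$per_type,
                  exclusivity = excl,
                  per_type = per_type)
  .write_table(detection, file.path(outdir, "detection.tsv"), "tsv")
  .write_table(do.call(rbind, roc_rows), file.path(outdir, "roc_summary.tsv"),
               "tsv")
  jsonlite::write_json(summary, file.path(outdir, "validation_summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  .stage_provenance(outdir, "validate", config)
  invisible(summary)
}

#' Report stage: one collected JSON report
#'
#' Gathers every quantity class the evaluation produces: discovery flag
#' counts, panel discriminators, model-comparison p-values, breakpoints,
#' most significant bins, detection fractions and medians, lead times
#' versus ROCA, exclusivity fractions, and the single/combined AUCs with
#' their difference p-values.
#'
#' @inheritParams run_simulate
#' @return the report list, invisibly.
#' @export
run_report <- function(config, outdir) {
  flags <- .read_table(.require_stage(file.path(outdir, "discovery_flags.tsv"),
                                      "discovery"))
  disc <- readLines(.require_stage(file.path(outdir, "panel_discriminators.txt"),
                                   "panel"))
  val <- jsonlite::read_json(.require_stage(
    file.path(outdir, "validation_summary.json"), "validate"),
    simplifyVector = TRUE)
  report <- list(discovery = list(n_proteins_tested = nrow(flags),
                                  n_flagged = sum(flags$flagged)),
                 panel = list(discriminators = disc),
                 validation = val)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  .stage_provenance(outdir, "report", config)
  invisible(report)
}

#' Run every pipeline stage in order
#'
#' @inheritParams run_simulate
#' @return the collected report, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  run_simulate(config, outdir)
  run_discovery(config, outdir)
  run_panel(config, outdir)
  run_validate(config, outdir)
  run_report(config, outdir)
}
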