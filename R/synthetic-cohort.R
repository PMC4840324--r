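#' @title Synthetic serial-serum cohort generator
#' @name synthetic_cohort
#' @description
#' Generates cohorts with the statistical structure the longitudinal
#' validation analysis assumes: stationary log-normal control marker levels
#' with a subject random effect, a responder subset of indolent (Type I)
#' cases whose Protein Z declines toward diagnosis after a changepoint, a
#' responder subset of aggressive (Type II) cases with a transient
#' mid-horizon elevation, and CA-125 case trajectories rising toward
#' diagnosis.  All draws derive from one integer seed, so the same
#' configuration reproduces the same cohort bit-for-bit.
NULL

#' Generator configuration
#'
#' Defaults emulate an annual serial-sampling ovarian-cancer screening
#' design: 31 controls, 19 Type I cases (10 borderline) and 30 Type II
#' cases, about six annual draws per subject over a 7-year horizon, with
#' the last case draw under 14 months before diagnosis.
#'
#' Marker scales and noise magnitudes are calibration constants, not taken
#' from any published measurement: control Protein Z geometric mean 1500
#' ng/ml with between-subject log-sd 0.25 and within-subject visit log-sd
#' 0.18 (plus replicate log-sd 0.05), control CA-125 geometric mean 13.5
#' U/ml.  They are chosen so that, at the default effect sizes, roughly
#' the responder subsets (8/19 Type I, 5/30 Type II) cross the empirical
#' percentile thresholds downstream.
#'
#' The Type I responder mean trajectory is flat at baseline earlier than
#' the changepoint `type1_changepoint` (420 days) and for `d <=`
#' changepoint is multiplied by
#' `1 - A * (exp(-d/tau) - exp(-t_c/tau)) / (1 - exp(-t_c/tau))`,
#' an exponential decay anchored so the multiplier is exactly `1 - A` at
#' diagnosis and exactly 1 at the changepoint.  On the post-changepoint
#' segment this is exactly the `c - A'*exp(-d/tau)` family fitted by
#' [fit_decay()].  Type II responders get a Gaussian bump in log space.
#'
#' @param n_control,n_type1,n_type2 subject counts (non-negative; at least
#'   one group must be non-empty).
#' @param n_borderline how many Type I subjects carry borderline histology.
#' @param visits_per_subject annual draws per subject.
#' @param horizon_days sampling horizon, days pre-diagnosis.
#' @param proz_log_mean,proz_sigma_b,proz_sigma_w,proz_sigma_rep,n_replicates
#'   control Protein Z law: log-mean, between-subject sd, within-subject sd,
#'   replicate (assay) sd, replicate count.
#' @param type1_responder_fraction,type1_changepoint,type1_decay Type I
#'   effect: responder fraction, changepoint t_c (days), and
#'   `list(amplitude, tau)` with amplitude the fractional drop at diagnosis.
#' @param type2_responder_fraction,type2_bump Type II effect: responder
#'   fraction and `list(center, width, height)` (days, days, fractional
#'   rise) of the log-space Gaussian bump.
#' @param ca125_log_mean,ca125_sigma_b,ca125_sigma_w control CA-125 law.
#' @param ca125_rise per-type case CA-125 rise:
#'   `list(type1 = list(amplitude, tau, onset), type2 = ..., subject_sd)`.
#' @param seed integer seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_control = 31L, n_type1 = 19L, n_type2 = 30L,
                             n_borderline = 10L,
                             visits_per_subject = 6L,
                             horizon_days = 2557,
                             proz_log_mean = log(1500),
                             proz_sigma_b = 0.25,
                             proz_sigma_w = 0.18,
                             proz_sigma_rep = 0.05,
                             n_replicates = 3L,
                             type1_responder_fraction = 8 / 19,
                             type1_changepoint = 420,
                             type1_decay = list(amplitude = 0.9, tau = 1000),
                             type2_responder_fraction = 5 / 30,
                             type2_bump = list(center = 1000, width = 300,
                                               height = 1.5),
                             ca125_log_mean = log(13.5),
                             ca125_sigma_b = 0.40,
                             ca125_sigma_w = 0.20,
                             ca125_rise = list(
                               type1 = list(amplitude = 4, tau = 300, onset = 420),
                               type2 = list(amplitude = 25, tau = 300, onset = 600),
                               subject_sd = 0.5),
                             seed = 1L) {
  cfg <- list(n_control = n_control, n_type1 = n_type1, n_type2 = n_type2,
              n_borderline = n_borderline,
              visits_per_subject = visits_per_subject,
              horizon_days = horizon_days,
              proz_log_mean = proz_log_mean, proz_sigma_b = proz_sigma_b,
              proz_sigma_w = proz_sigma_w, proz_sigma_rep = proz_sigma_rep,
              n_replicates = n_replicates,
              type1_responder_fraction = type1_responder_fraction,
              type1_changepoint = type1_changepoint,
              type1_decay = type1_decay,
              type2_responder_fraction = type2_responder_fraction,
              type2_bump = type2_bump,
              ca125_log_mean = ca125_log_mean,
              ca125_sigma_b = ca125_sigma_b, ca125_sigma_w = ca125_sigma_w,
              ca125_rise = ca125_rise,
              seed = seed)
  class(cfg) <- "generator_config"
  .validate_generator_config(cfg)
  cfg
}

.validate_generator_config <- function(cfg) {
  counts <- c(cfg$n_control, cfg$n_type1, cfg$n_type2)
  if (any(counts < 0)) stop("subject counts must be non-negative")
  if (sum(counts) == 0) stop("at least one subject group must be non-empty")
  fr <- c(cfg$type1_responder_fraction, cfg$type2_responder_fraction)
  if (any(fr < 0 | fr > 1)) stop("responder fractions must lie in [0, 1]")
  if (cfg$proz_sigma_b <= 0 || cfg$proz_sigma_w <= 0) {
    stop("log-sd parameters must be positive")
  }
  if (cfg$type1_decay$tau <= 0 || cfg$type2_bump$width <= 0) {
    stop("tau and bump width must be positive")
  }
  tc <- cfg$type1_changepoint
  m <- cfg$type2_bump$center
  if (tc <= 0 || tc > cfg$horizon_days || m <= 0 || m > cfg$horizon_days) {
    stop("changepoint and bump center must lie in (0, horizon_days]")
  }
  invisible(cfg)
}

# Type I responder multiplier on the natural scale: 1 at d >= t_c,
# 1 - A at d = 0, exponential (time constant tau) in between.
.type1_multiplier <- function(d, amplitude, tau, t_c) {
  k0 <- exp(-t_c / tau)
  g <- ifelse(d >= t_c, 0, (exp(-d / tau) - k0) / (1 - k0))
  1 - amplitude * g
}

.type2_multiplier <- function(d, height, center, width) {
  1 + height * exp(-(d - center)^2 / (2 * width^2))
}

.ca125_multiplier <- function(d, amplitude, tau, onset) {
  k0 <- exp(-onset / tau)
  g <- ifelse(d >= onset, 0, (exp(-d / tau) - k0) / (1 - k0))
  1 + amplitude * g
}

#' Simulate a serial-serum screening cohort
#'
#' @param config a [generator_config()].
#' @return list with elements `manifest` (a validated [cohort_manifest()])
#'   and `truth` (one row per subject: responder flag, subject baseline on
#'   the log scale, and the trajectory parameters in force).
#' @examples
#' sim <- simulate_cohort(generator_config(seed = 7))
#' sim$manifest
#' @export
simulate_cohort <- function(config = generator_config()) {
  .validate_generator_config(config)
  cfg <- config
  set.seed(cfg$seed)

  n_total <- cfg$n_control + cfg$n_type1 + cfg$n_type2
  group <- rep(c("control", "case", "case"),
               c(cfg$n_control, cfg$n_type1, cfg$n_type2))
  cancer_type <- rep(c("none", "type1", "type2"),
                     c(cfg$n_control, cfg$n_type1, cfg$n_type2))
  subject_id <- sprintf("S%03d", seq_len(n_total))

  histology <- character(n_total)
  stage <- rep("none", n_total)
  i1 <- which(cancer_type == "type1")
  i2 <- which(cancer_type == "type2")
  histology[cancer_type == "none"] <- "none"
  if (length(i1) > 0L) {
    nb <- min(cfg$n_borderline, length(i1))
    histology[i1] <- c(rep("borderline", nb),
                       rep("invasive", length(i1) - nb))
    stage[i1] <- sample(c("I", "II", "III"), length(i1), replace = TRUE,
                        prob = c(14, 1, 4) / 19)
  }
  if (length(i2) > 0L) {
    histology[i2] <- "high-grade serous"
    stage[i2] <- sample(c("I", "II", "III"), length(i2), replace = TRUE,
                        prob = c(7, 8, 15) / 30)
  }
  age <- round(stats::rnorm(n_total, 62, 5), 1)

  # responder subsets
  responder <- rep(FALSE, n_total)
  if (length(i1) > 0L) {
    n_resp1 <- round(cfg$type1_responder_fraction * length(i1))
    responder[i1[seq_len(n_resp1)]] <- TRUE
  }
  if (length(i2) > 0L) {
    n_resp2 <- round(cfg$type2_responder_fraction * length(i2))
    responder[i2[seq_len(n_resp2)]] <- TRUE
  }

  # visit schedule: annual draws with jitter, last case draw < 14 months
  k <- max(1L, round(cfg$visits_per_subject))
  is_case <- group == "case"
  d_last <- ifelse(is_case, stats::runif(n_total, 30, 400),
                   stats::runif(n_total, 30, 426))
  offsets <- outer(365 * (seq_len(k) - 1L), rep(1, n_total))
  jitter <- matrix(stats::rnorm(k * n_total, 0, 20), nrow = k)
  jitter[1L, ] <- 0
  days <- sweep(offsets + jitter, 2L, d_last, "+")
  days <- pmin(pmax(days, 0), cfg$horizon_days)

  d <- as.numeric(days)           # k x n_total matrix, column-major
  subj_of_sample <- rep(seq_len(n_total), each = k)

  # Protein Z
  b <- stats::rnorm(n_total, 0, cfg$proz_sigma_b)
  shift <- numeric(length(d))
  t1 <- responder[subj_of_sample] & cancer_type[subj_of_sample] == "type1"
  t2 <- responder[subj_of_sample] & cancer_type[subj_of_sample] == "type2"
  shift[t1] <- log(.type1_multiplier(d[t1], cfg$type1_decay$amplitude,
                                     cfg$type1_decay$tau,
                                     cfg$type1_changepoint))
  shift[t2] <- log(.type2_multiplier(d[t2], cfg$type2_bump$height,
                                     cfg$type2_bump$center,
                                     cfg$type2_bump$width))
  log_true <- cfg$proz_log_mean + b[subj_of_sample] + shift +
    stats::rnorm(length(d), 0, cfg$proz_sigma_w)
  nrep <- max(1L, cfg$n_replicates)
  reps <- matrix(exp(log_true + stats::rnorm(length(d) * nrep, 0,
                                             cfg$proz_sigma_rep)),
                 nrow = length(d), ncol = nrep)

  # CA-125
  b_ca <- stats::rnorm(n_total, 0, cfg$ca125_sigma_b)
  amp_subj <- exp(stats::rnorm(n_total, 0, cfg$ca125_rise$subject_sd))
  rise <- rep(1, length(d))
  c1 <- cancer_type[subj_of_sample] == "type1"
  c2 <- cancer_type[subj_of_sample] == "type2"
  r1 <- cfg$ca125_rise$type1
  r2 <- cfg$ca125_rise$type2
  rise[c1] <- .ca125_multiplier(d[c1], r1$amplitude * amp_subj[subj_of_sample[c1]],
                                r1$tau, r1$onset)
  rise[c2] <- .ca125_multiplier(d[c2], r2$amplitude * amp_subj[subj_of_sample[c2]],
                                r2$tau, r2$onset)
  ca125 <- exp(cfg$ca125_log_mean + b_ca[subj_of_sample] +
                 stats::rnorm(length(d), 0, cfg$ca125_sigma_w)) * rise

  roca_class <- ifelse(ca125 > 35, "elevated",
                       ifelse(ca125 > 22, "intermediate", "normal"))

  samples <- data.frame(subject_id = subject_id[subj_of_sample],
                        days_to_diagnosis = d,
                        ca125 = ca125,
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrep)) samples[[paste0("proz_rep", r)]] <- reps[, r]
  samples$roca_class <- roca_class

  matched_case <- rep(NA_character_, n_total)
  ctrl <- which(group == "control")
  cases <- which(group == "case")
  if (length(ctrl) > 0L && length(cases) > 0L) {
    matched_case[ctrl] <- subject_id[cases[((seq_along(ctrl) - 1L) %%
                                              length(cases)) + 1L]]
  }
  subjects <- data.frame(subject_id = subject_id, group = group,
                         cancer_type = cancer_type, histology = histology,
                         stage = stage, age_at_randomisation = age,
                         matched_case = matched_case,
                         stringsAsFactors = FALSE)

  truth <- data.frame(subject_id = subject_id, group = group,
                      cancer_type = cancer_type, responder = responder,
                      baseline_log = cfg$proz_log_mean + b,
                      amplitude = ifelse(cancer_type == "type1" & responder,
                                         cfg$type1_decay$amplitude,
                                         ifelse(cancer_type == "type2" & responder,
                                                cfg$type2_bump$height, 0)),
                      tau = ifelse(cancer_type == "type1" & responder,
                                   cfg$type1_decay$tau, NA_real_),
                      changepoint = ifelse(cancer_type == "type1" & responder,
                                           cfg$type1_changepoint, NA_real_),
                      stringsAsFactors = FALSE)

  list(manifest = cohort_manifest(subjects, samples), truth = truth)
}

#' Default 8-plex isobaric labelling design
#'
#' Six experimental channels plus two duplicate reference channels (119 and
#' 121) labelling the same pooled sample, used to estimate the technical
#' log-ratio variation of the workflow.
#'
#' @param case_channels,control_channels,reference_channels channel names.
#' @return a `pool_design` list.
#' @export
itraq_design <- function(case_channels = c("113", "114", "115", "116"),
                         control_channels = c("117", "118"),
                         reference_channels = c("119", "121")) {
  if (length(reference_channels) != 2L) {
    stop("the design needs exactly two duplicate reference channels")
  }
  structure(list(case = case_channels, control = control_channels,
                 reference = reference_channels,
                 channels = c(case_channels, control_channels,
                              reference_channels)),
            class = "pool_design")
}

#' Simulate a peptide-level reporter-intensity table
#'
#' Each peptide gets a log-normal base intensity; each channel observes it
#' under multiplicative log2-normal noise.  Spiked proteins are shifted on
#' the case channels by their stated log2 effect.  The two duplicate
#' reference channels label the same pool and therefore differ only by
#' noise.
#'
#' @param n_proteins,n_peptides_per_protein table dimensions; at least two
#'   peptides per protein are required (the protein estimation rule).
#' @param design a [itraq_design()].
#' @param effects numeric vector of per-protein log2 fold changes (recycled
#'   to `n_proteins`; default all zero).
#' @param noise_sd technical log2 noise sd per (peptide, channel).
#' @param identification_p optional per-protein identification p-values to
#'   carry through (default: all 0.001, i.e. confidently identified).
#' @param seed integer seed.
#' @return list with `table` (data frame: `protein_id`, `peptide_id`,
#'   `identification_p`, one intensity column per channel) and `truth`
#'   (per-protein true log2 effect).
#' @export
simulate_peptide_table <- function(n_proteins, n_peptides_per_protein,
                                   design = itraq_design(),
                                   effects = 0, noise_sd = 0.1,
                                   identification_p = 0.001,
                                   seed = 1L) {
  if (n_peptides_per_protein < 2L) {
    stop("at least 2 peptides per protein are required (protein estimation rule)")
  }
  set.seed(seed)
  effects <- rep_len(effects, n_proteins)
  identification_p <- rep_len(identification_p, n_proteins)
  n_pep <- n_proteins * n_peptides_per_protein
  protein_id <- rep(sprintf("P%04d", seq_len(n_proteins)),
                    each = n_peptides_per_protein)
  peptide_id <- sprintf("%s_pep%d", protein_id,
                        rep(seq_len(n_peptides_per_protein), n_proteins))
  base_log2 <- stats::rnorm(n_pep, 16, 1.5)
  tab <- data.frame(protein_id = protein_id, peptide_id = peptide_id,
                    identification_p = rep(identification_p,
                                           each = n_peptides_per_protein),
                    stringsAsFactors = FALSE)
  eff_pep <- rep(effects, each = n_peptides_per_protein)
  for (ch in design$channels) {
    shift <- if (ch %in% design$case) eff_pep else 0
    noise <- if (noise_sd > 0) stats::rnorm(n_pep, 0, noise_sd) else 0
    tab[[ch]] <- 2^(base_log2 + shift + noise)
  }
  list(table = tab,
       truth = data.frame(protein_id = sprintf("P%04d", seq_len(n_proteins)),
                          log2_effect = effects, stringsAsFactors = FALSE))
}

#' Assign subjects' samples to discovery pools
#'
#' Reproduces the pooled discovery design: for each subject one sample close
#' to diagnosis (strictly under `early_max` days, the draw nearest
#' diagnosis) and one far from it (strictly over `far_min` days, the
#' earliest draw), pooled within cancer type and window.  With both case
#' types and controls present this yields six pools.  The pooled marker
#' value is the mean over members.
#'
#' @param m a `cohort_manifest`.
#' @param early_max,far_min window edges in days (defaults 426 and 973,
#'   i.e. under 14 months and over 32 months pre-diagnosis).
#' @return list with `members` (pool, subject_id, days_to_diagnosis, proz,
#'   ca125), `pooled` (pool, n, mean proz, mean ca125) and `exclusions`
#'   (subjects lacking a window, with the window named).
#' @export
select_discovery_pools <- function(m, early_max = 426, far_min = 973) {
  validate_manifest(m)
  s <- merge(m$samples, m$subjects[c("subject_id", "cancer_type")],
             by = "subject_id")
  grp <- ifelse(s$cancer_type == "none", "control", s$cancer_type)
  members <- list()
  exclusions <- list()
  for (sid in unique(s$subject_id)) {
    rows <- s[s$subject_id == sid, , drop = FALSE]
    g <- grp[match(sid, s$subject_id)]
    early <- rows[rows$days_to_diagnosis < early_max, , drop = FALSE]
    far <- rows[rows$days_to_diagnosis > far_min, , drop = FALSE]
    if (nrow(early) > 0L) {
      pick <- early[which.min(early$days_to_diagnosis), , drop = FALSE]
      members[[length(members) + 1L]] <-
        data.frame(pool = paste0(g, "_early"), subject_id = sid,
                   days_to_diagnosis = pick$days_to_diagnosis,
                   proz = pick$proz, ca125 = pick$ca125,
                   stringsAsFactors = FALSE)
    } else {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(subject_id = sid, missing_window = "early",
                   stringsAsFactors = FALSE)
    }
    if (nrow(far) > 0L) {
      pick <- far[which.max(far$days_to_diagnosis), , drop = FALSE]
      members[[length(members) + 1L]] <-
        data.frame(pool = paste0(g, "_far"), subject_id = sid,
                   days_to_diagnosis = pick$days_to_diagnosis,
                   proz = pick$proz, ca125 = pick$ca125,
                   stringsAsFactors = FALSE)
    } else {
      exclusions[[length(exclusions) + 1L]] <-
        data.frame(subject_id = sid, missing_window = "far",
                   stringsAsFactors = FALSE)
    }
  }
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(pool = character(), subject_id = character(),
               days_to_diagnosis = numeric(), proz = numeric(),
               ca125 = numeric())
  pooled <- if (nrow(members)) {
    agg <- stats::aggregate(members[c("proz", "ca125")],
                            by = list(pool = members$pool), FUN = mean)
    n <- stats::aggregate(list(n = members$subject_id),
                          by = list(pool = members$pool), FUN = length)
    merge(n, agg, by = "pool")
  } else {
    data.frame(pool = character(), n = integer(), proz = numeric(),
               ca125 = numeric())
  }
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(subject_id = character(), missing_window = character())
  list(members = members, pooled = pooled, exclusions = exclusions)
}
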