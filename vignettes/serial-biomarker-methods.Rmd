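---
title: "Methods: serial serum biomarker evaluation with serodetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serial serum biomarker evaluation with serodetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serodetect)
```

## The problem

Ovarian cancer is usually diagnosed late, when survival is poor.  Serial
serum collections from screening trials make it possible to ask whether a
candidate protein marker changes *before* clinical diagnosis, and by how
much it could anticipate existing tools — CA-125 interpreted through a
longitudinal risk algorithm (ROCA).  serodetect implements a three-stage
evaluation of such a candidate:

1. **Pooled discovery** — isobaric-tag (iTRAQ) reporter-ion quantification
   of pooled sera, filtered for proteins whose relative ratios exceed
   purely technical variation;
2. **Targeted panel verification** — replicate-run protein abundances for a
   short panel, volcano-classified per stratum (cancer type × time
   window), keeping proteins that discriminate in *every* stratum;
3. **Longitudinal validation** — serial per-subject trajectories of the
   surviving marker (here, Protein Z in ng/ml) against CA-125 (U/ml):
   trend smoothing and breakpoint estimation, a nested flat-versus-decay
   model comparison, binned rank tests, empirical percentile detection
   thresholds with lead-time accounting, and ROC analysis of the combined
   two-marker panel.

Because the original trial sera are not publicly available, the package is
driven by a synthetic-cohort generator that reproduces the *statistical
design* of the study: 80 subjects (19 indolent "Type I" cases including 10
borderline tumours, 30 aggressive "Type II" cases, 31 matched controls),
about six annual serum draws each, 482 samples in all, spanning up to 7
years pre-diagnosis.  Time is recorded as non-negative days before
diagnosis (controls inherit the index date of their matched case); larger
values are earlier.

## The synthetic cohort model

Control Protein Z is stationary log-normal with a subject random effect:

$$\log Y_{ij} = \mu_c + b_i + e_{ij}, \qquad
  b_i \sim N(0, \sigma_b^2),\; e_{ij} \sim N(0, \sigma_w^2),$$

plus replicate-level assay noise (each draw is measured in triplicate and
analysed as the replicate mean).  The scale and noise constants are *not*
published values; they are calibration choices fixed once at design time:
geometric mean 1500 ng/ml, $\sigma_b = 0.25$, $\sigma_w = 0.18$, replicate
sd 0.05.  They were chosen so that, with the default effect sizes below,
the fraction of cases crossing the percentile thresholds is of the same
order as the study's reported 8/19 (Type I) and 5/30 (Type II).

**Type I effect.**  A responder subset (default 8/19) declines toward
diagnosis after a changepoint $t_c = 420$ days.  The mean multiplier is 1
for $d \ge t_c$ and, for $d \le t_c$,

$$m(d) = 1 - A\,\frac{e^{-d/\tau} - e^{-t_c/\tau}}{1 - e^{-t_c/\tau}},$$

an exponential decay *anchored* so that $m(t_c) = 1$ (no effect at onset)
and $m(0) = 1 - A$ exactly (defaults $A = 0.9$, $\tau = 1000$ d).  Two
properties motivated this form over an unanchored exponential applied at
all lags.  First, an unanchored decay never actually begins anywhere: the
declared changepoint would have no effect on the generated data, and the
maximum-curvature point of any smoothed trajectory would sit at diagnosis
rather than at onset, making breakpoint recovery ill-posed.  Second, on
the post-onset segment $d \le t_c$ the anchored form is *exactly* the
fitted family $c - A' e^{-d/\tau}$ with the same $\tau$, so parameter
recovery is well-defined.  The default $\tau = 1000$ d gives a gentle,
near-linear post-onset decline, which concentrates trajectory curvature at
the onset — the regime in which an "inflection point" of a smoothed trend
is a meaningful quantity.

**Type II effect.**  A responder subset (default 5/30) has a transient
log-space Gaussian elevation centred at 1000 days (width 300 d, fractional
rise 1.5), emulating a rise-and-return between roughly 1500 and 500 days
pre-diagnosis.  **CA-125** rises toward diagnosis in cases with the same
anchored-onset family (amplitudes 4 and 25 for Type I/II, $\tau = 300$ d),
with log-normal subject heterogeneity; per-sample ROCA-style
classifications (`normal`/`intermediate`/`elevated`) are derived from the
simulated CA-125 and consumed downstream as annotations only.

Visit times are annual with 20-day jitter; the last case draw falls under
14 months pre-diagnosis, so every case has samples in both discovery
windows (< 14 months, > 32 months).  One integer seed drives the whole
cohort; identical seeds give bit-identical cohorts.

What the generator does **not** emulate: assay drift and batch effects,
informative missed visits, non-log-normal heavy tails, correlations
between CA-125 and Protein Z beyond their shared time course, and any
spectrum-level structure (no m/z, no chromatograms).  Green tests
therefore certify the *statistical machinery* under the declared design,
not performance on real sera.

## Discovery filtering

Per-peptide log2 ratios between two reporter channels are aggregated per
protein by the **median** (robust; the aggregation rule is a package
choice).  Proteins need at least two usable peptides; peptides with
non-positive intensity are dropped and counted.  The two duplicate
reference channels (119/121), which label the same pooled sample, yield
protein-level log2 ratios whose spread is purely technical; the interval
mean ± 1.96 sd (95% coverage, normal approximation; a percentile variant
is available) defines the significance band.  A protein is flagged iff

* upstream identification p < 0.05 (carried as an input column — database
  searching is out of scope),
* at least two peptides, and
* log2 ratio outside the technical interval.

The interval is computed on the log scale; whether the original workflow
used log or raw ratios is unstated, and the choice is recorded in the
output metadata.

## Panel verification

Protein abundance per run is the mean of per-peptide log2 intensities
(≥ 2 peptides).  Each stratum compares case versus control pools across
triplicate runs with a two-sample t statistic on the replicate
abundances; n = 3 per side is the design's replicate unit and is
documented in the output.  Volcano classes require *both* at least a
twofold change (|log2 fc| ≥ 1; the boundary is sharp, 0.99 does not
qualify) and p < 0.05.  The panel's discriminators are the proteins whose
class is not `ns` in all four strata.

## Trajectory analysis

* **Loess trend**: locally weighted linear regression (tricube weights,
  degree 1) evaluated exactly on a 1-day grid.  The span default is 0.75
  for trend display; **breakpoint estimation uses span 0.3**, since
  maximum-curvature localisation needs a narrower bandwidth than smooth
  display — with a wide span the onset bend is smeared hundreds of days
  toward the data-dense side.
* **Breakpoint**: the interior grid point maximising |second difference|
  of the smoothed curve.  The outer 10% of the grid at each end is
  excluded (boundary curvature of a local fit is unreliable), and a curve
  whose total variation is below 5% of its median level is declared flat
  (sentinel `NA`) — a noisy control trend should not yield a breakpoint.
* **Decay model**: $y(d) = c - A e^{-d/\tau}$ with $A \ge 0$,
  $\tau \in [1, 10 \cdot \max d]$.  At fixed $\tau$ the problem is linear
  in $(c, A)$, so the fit profiles $\tau$ over the multistart grid
  {30, 100, 300, 1000, 3000} days and refines the best start by
  one-dimensional optimisation on $\log \tau$.  Because $A = 0$ is
  admissible, rss(decay) ≤ rss(flat) always — the models are properly
  nested, and on flat data the decay fit degenerates gracefully.
* **Model comparison**: the statistic $n \log(\mathrm{rss}_\mathrm{flat} /
  \mathrm{rss}_\mathrm{decay})$ is unit-free.  The null distribution is
  built at the subject level from the flat-model reconstruction: each
  residual is split into its subject mean plus a within-subject
  deviation, and a null replicate permutes the deviations across each
  subject's own visits while keeping days and subject means in place.
  This preserves the grouping structure while destroying any alignment
  between deviation and time.  A subject bootstrap *with replacement* was
  evaluated for this null and rejected: duplicated day patterns let the
  decay model chase repeated clusters, inflating the null statistics and
  driving the empirical type-I error to essentially zero; the permutation
  null holds the nominal 5% level.  The p-value carries the add-one
  correction.  Which procedure produced the original study's
  model-comparison p-value is unstated; equivalence is not claimed.
* **Binned tests**: 60-week bins, left-closed/right-open, anchored at
  diagnosis, tiling 0–420 weeks.  Case levels per bin are compared
  against the *full* control pool (whether the original analysis
  time-restricted controls per bin is unstated; the all-control reference
  is the more stable choice) with an unpaired Mann–Whitney test using the
  tie-corrected normal approximation.  An unpaired test is used although
  the study's methods section names the signed-rank family: bins hold
  unequal, unpaired case subsets against pooled controls, where a paired
  signed-rank test is undefined.  Raw p-values are reported alongside
  Benjamini–Hochberg adjusted ones; bins with fewer than three case
  samples are marked underpowered.

## Detection thresholds and lead time

Thresholds are the empirical 1st and 99th percentiles of *all* control
samples — an empirical ~1% false-positive rule per direction — using
linear interpolation between order statistics (R quantile type 7; the
study does not state its estimator, so the convention is fixed and
recorded).  Fitting on all control samples reproduces the original
design, which is leaky at the subject level; a subject-aware variant can
be obtained simply by fitting thresholds on a held-out control subset.
Crossing is strict inequality on the replicate-mean level; Type I uses
the low threshold, Type II the high one; CA-125 detection is strictly
above 35 U/ml (the clinical referral cut-off), applied to any sample of
the subject (whether the original comparison used maximum or latest value
is unstated).  First detection is the *earliest* crossing sample (largest
days value), matching the lead-time emphasis; lead versus ROCA is first
detection minus the subject's first ROCA-positive sample.

## ROC analysis

Single-marker AUC is the rank statistic (ties half), identical to the
trapezoid area of the threshold-sweep curve.  The combined panel
log10(x+1)-transforms both markers, standardises with training-fold
parameters, and trains a linear-kernel SVM (cost 1) per cross-validation
fold, with **folds assigned by subject** so serial samples never straddle
train and test; out-of-fold decision scores are pooled into one ROC.
This out-of-fold scoring is stricter than an apparent (resubstitution)
ROC; the original construction is unstated.  AUC differences on the same
samples are tested by a paired subject-level bootstrap with the null
centred at zero and add-one correction.  Classification is per sample
(case sample versus control sample), matching the per-point presentation
of the serial data.

## Problem sizes and runtime choices

The shipped tests exercise the machinery at desk scale, chosen as the
smallest sizes at which the checked properties are stable: calibration
suites use 100–200 replicates of 80–160-sample datasets with 2000
permutation/bootstrap replicates each; threshold calibration uses a
10,000-measurement training set and a 100,000-measurement held-out set;
breakpoint recovery uses an 800-subject responder cohort at the default
noise level; the end-to-end run uses the packaged 482-sample cohort.

## Known limitations

* The packaged cohort is synthetic; the study's headline values
  (p-values, AUCs, detection medians) derive from unavailable sera and
  are reproduced as *quantity classes*, not numbers.
* The discovery stage treats identification confidence as an input;
  database searching, spectral libraries and retention-time calibration
  are out of scope, as are the ROCA algorithm's internals.
* Per-stratum panel inference rests on n = 3 pooled replicate runs, as in
  the verification design; it is a screening filter, not a
  mixed-model analysis.
* The percentile thresholds are in-sample for controls by design;
  reported control false-positive rates on the fitting set are therefore
  optimistic at the subject level.
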