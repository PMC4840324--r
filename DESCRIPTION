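Package: serodetect
Title: Serial Serum Biomarker Evaluation for Pre-Diagnostic Cancer Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage evaluation pipeline for candidate serum biomarkers
    of early ovarian cancer. Stage one filters pooled isobaric-tag (iTRAQ)
    protein ratios against a technical-variation confidence interval derived
    from duplicate reference channels. Stage two verifies a targeted protein
    panel with per-stratum volcano classification of SWATH-style replicate
    abundances. Stage three analyses longitudinal serial serum samples:
    loess trend smoothing with breakpoint estimation, nested
    flat-versus-exponential-decay model comparison with a subject-level
    bootstrap, 60-week binned rank tests, empirical percentile detection
    thresholds with lead-time accounting against CA-125 and ROCA
    classifications, and ROC analysis of single markers and an SVM-combined
    two-marker panel. A seedable synthetic-cohort generator emulating an
    annual serial-sampling screening design makes every stage testable
    without access to trial sera.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
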