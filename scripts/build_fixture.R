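#!/usr/bin/env Rscript
# Regenerates the packaged synthetic cohort under inst/extdata from code.
# Run from the repository root.
pkgload::load_all(".", quiet = TRUE)
m <- build_fixture_cohort()
stopifnot(nrow(m$subjects) == 80L, nrow(m$samples) == 482L)
write_cohort(m,
             file.path("inst", "extdata", "synthetic_cohort_subjects.tsv"),
             file.path("inst", "extdata", "synthetic_cohort_samples.tsv"))
cat("fixture written:", nrow(m$subjects), "subjects,",
    nrow(m$samples), "samples\n")
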