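# Shared in-code fixtures.

# A minimal hand-built cohort: one control, one Type I case, one Type II
# case, two samples each.
tiny_manifest <- function() {
  subjects <- data.frame(
    subject_id = c("C1", "T1", "T2"),
    group = c("control", "case", "case"),
    cancer_type = c("none", "type1", "type2"),
    histology = c("none", "borderline serous", "high-grade serous"),
    stage = c("none", "I", "III"),
    age_at_randomisation = c(61, 64, 60),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    subject_id = rep(c("C1", "T1", "T2"), each = 2),
    days_to_diagnosis = c(100, 1200, 90, 1100, 80, 1000),
    ca125 = c(12, 14, 20, 11, 80, 15),
    proz_rep1 = c(1500, 1480, 700, 1450, 2600, 1520),
    proz_rep2 = c(1510, 1490, 710, 1460, 2610, 1530),
    proz_rep3 = c(1505, 1485, 705, 1455, 2605, 1525),
    roca_class = c("normal", "normal", "intermediate", "normal",
                   "elevated", "normal"),
    stringsAsFactors = FALSE)
  cohort_manifest(subjects, samples)
}

# peptide table built by hand: intensities chosen so per-peptide ratios are
# exact powers of two
toy_peptide_table <- function() {
  data.frame(
    protein_id = c("A", "A", "B", "B", "B", "C"),
    peptide_id = c("A_1", "A_2", "B_1", "B_2", "B_3", "C_1"),
    identification_p = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001),
    ch_case = c(200, 400, 100, 100, 100, 50),
    ch_ctrl = c(100, 200, 100, 100, 100, 50),
    ref_a = c(100, 100, 100, 100, 100, 100),
    ref_b = c(100, 100, 100, 100, 100, 100),
    stringsAsFactors = FALSE)
}
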