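#' @title Cohort containers and tabular input/output
#' @name cohort_io
#' @description
#' A cohort is represented as a `cohort_manifest`: a validated pair of plain
#' data frames, one row per subject and one row per serum draw.  Time is
#' stored as non-negative days before diagnosis (cases) or before the matched
#' index date (controls); larger values are earlier.  Marker columns are
#' CA-125 in U/ml and Protein Z in ng/ml, the latter as the mean of its
#' replicate wells.
NULL

.group_levels <- c("control", "case")
.cancer_levels <- c("none", "type1", "type2")
.stage_levels <- c("none", "I", "II", "III")
.roca_levels <- c("normal", "intermediate", "elevated", "missing")

.subject_cols <- c("subject_id", "group", "cancer_type", "histology",
                   "stage", "age_at_randomisation")
.sample_cols <- c("subject_id", "days_to_diagnosis", "ca125", "roca_class")

#' Construct and validate a cohort manifest
#'
#' @param subjects data frame with columns `subject_id`, `group`
#'   (`control`/`case`), `cancer_type` (`none`/`type1`/`type2`), `histology`,
#'   `stage` (`none`/`I`/`II`/`III`), `age_at_randomisation`, and optionally
#'   `matched_case` (for controls, the `subject_id` of the matched case whose
#'   index date they inherit).
#' @param samples data frame with columns `subject_id`, `days_to_diagnosis`,
#'   `ca125`, replicate columns `proz_rep1`, `proz_rep2`, ... and
#'   `roca_class`.  A `proz` column (mean of non-missing replicates) is
#'   (re)computed on construction.
#' @param validate if `TRUE` (default) all invariants are checked.
#' @return object of class `cohort_manifest` (list with `subjects`,
#'   `samples`).
#' @export
cohort_manifest <- function(subjects, samples, validate = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  rep_cols <- grep("^proz_rep[0-9]+$", names(samples), value = TRUE)
  if (length(rep_cols) == 0L && "proz" %in% names(samples)) {
    # single-measurement tables: treat proz as its own sole replicate
    samples$proz_rep1 <- samples$proz
    rep_cols <- "proz_rep1"
  }
  if (length(rep_cols) > 0L && nrow(samples) > 0L) {
    reps <- as.matrix(samples[rep_cols])
    samples$proz <- rowMeans(reps, na.rm = TRUE)
    samples$proz[!is.finite(samples$proz)] <- NA_real_
  } else if (!("proz" %in% names(samples))) {
    samples$proz <- numeric(nrow(samples))
  }
  m <- structure(list(subjects = subjects, samples = samples),
                 class = "cohort_manifest")
  if (validate) validate_manifest(m)
  m
}

#' Validate a cohort manifest
#'
#' Checks the schema (required columns present), the controlled vocabularies,
#' the control/case consistency rules (`group = control` iff
#' `cancer_type = none` iff `stage = none`), uniqueness of subject ids,
#' referential integrity of samples, non-negativity of times and marker
#' levels, and that `proz` equals the replicate mean to within 1e-9 relative.
#'
#' @param m a `cohort_manifest`.
#' @return `m`, invisibly.  Stops with a classed condition on violation:
#'   `serodetect_schema_error` names the missing column,
#'   `serodetect_integrity_error` lists the orphan subject ids.
#' @export
validate_manifest <- function(m) {
  stopifnot(inherits(m, "cohort_manifest"))
  subjects <- m$subjects
  samples <- m$samples
  for (col in .subject_cols) {
    if (!col %in% names(subjects)) {
      stop(.schema_error(sprintf("subjects table is missing column '%s'", col)))
    }
  }
  for (col in .sample_cols) {
    if (!col %in% names(samples)) {
      stop(.schema_error(sprintf("samples table is missing column '%s'", col)))
    }
  }
  if (anyDuplicated(subjects$subject_id)) {
    dup <- unique(subjects$subject_id[duplicated(subjects$subject_id)])
    stop(.integrity_error(sprintf("duplicated subject_id: %s",
                                  paste(dup, collapse = ", "))))
  }
  .check_vocab(subjects$group, .group_levels, "group")
  .check_vocab(subjects$cancer_type, .cancer_levels, "cancer_type")
  .check_vocab(subjects$stage, .stage_levels, "stage")
  if (nrow(samples) > 0L) .check_vocab(samples$roca_class, .roca_levels, "roca_class")

  is_control <- subjects$group == "control"
  bad <- (is_control & (subjects$cancer_type != "none" | subjects$stage != "none")) |
    (!is_control & subjects$cancer_type == "none")
  if (any(bad)) {
    stop(.integrity_error(sprintf(
      "group/cancer_type/stage inconsistent for subject(s): %s",
      paste(subjects$subject_id[bad], collapse = ", "))))
  }
  orphan <- setdiff(samples$subject_id, subjects$subject_id)
  if (length(orphan) > 0L) {
    stop(.integrity_error(sprintf(
      "samples reference unknown subject_id(s): %s",
      paste(sort(unique(orphan)), collapse = ", "))))
  }
  if (nrow(samples) > 0L) {
    if (any(samples$days_to_diagnosis < 0, na.rm = TRUE)) {
      stop(.integrity_error("days_to_diagnosis must be non-negative"))
    }
    if (any(samples$ca125 < 0, na.rm = TRUE)) {
      stop(.integrity_error("ca125 must be non-negative"))
    }
    rep_cols <- grep("^proz_rep[0-9]+$", names(samples), value = TRUE)
    if (length(rep_cols) > 0L) {
      mu <- rowMeans(as.matrix(samples[rep_cols]), na.rm = TRUE)
      ok <- is.na(samples$proz) | !is.finite(mu) |
        abs(samples$proz - mu) <= 1e-9 * pmax(1, abs(mu))
      if (!all(ok)) {
        stop(.integrity_error("proz does not equal the mean of its replicates"))
      }
    }
  }
  invisible(m)
}

.schema_error <- function(msg) {
  structure(class = c("serodetect_schema_error", "error", "condition"),
            list(message = msg, call = NULL))
}

.integrity_error <- function(msg) {
  structure(class = c("serodetect_integrity_error", "error", "condition"),
            list(message = msg, call = NULL))
}

.check_vocab <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(.schema_error(sprintf("column '%s' contains values outside {%s}: %s",
                               what, paste(levels, collapse = ", "),
                               paste(unique(x[bad]), collapse = ", "))))
  }
}

#' @export
print.cohort_manifest <- function(x, ...) {
  tab <- table(factor(x$subjects$cancer_type, levels = .cancer_levels))
  cat(sprintf("cohort_manifest: %d subjects (%d control, %d type1, %d type2), %d samples\n",
              nrow(x$subjects), tab[["none"]], tab[["type1"]], tab[["type2"]],
              nrow(x$samples)))
  invisible(x)
}

.read_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  format <- match.arg(format, c("csv", "tsv"))
  sep <- if (format == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8", comment.char = "")
}

.write_table <- function(df, path, format) {
  sep <- if (format == "csv") "," else "\t"
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop(sprintf("cannot write '%s': %s", path,
                                conditionMessage(ok)))
  invisible(path)
}

#' Read a cohort from subject and sample tables
#'
#' @param subjects_path,samples_path paths to delimited tables with header
#'   rows (see [cohort_manifest()] for the column contract).  Alternatively
#'   `subjects_path` may be a directory containing `subjects.<ext>` and
#'   `samples.<ext>`.
#' @param format `"csv"` or `"tsv"`; inferred from the file extension when
#'   `NULL`.
#' @return a validated [cohort_manifest()].
#' @export
read_cohort <- function(subjects_path, samples_path = NULL, format = NULL) {
  if (is.null(samples_path) && dir.exists(subjects_path)) {
    ext <- if (identical(format, "csv")) "csv" else "tsv"
    dir <- subjects_path
    subjects_path <- file.path(dir, paste0("subjects.", ext))
    samples_path <- file.path(dir, paste0("samples.", ext))
  }
  subjects <- .read_table(subjects_path, format)
  samples <- .read_table(samples_path, format)
  cohort_manifest(subjects, samples, validate = TRUE)
}

#' Write a cohort to subject and sample tables
#'
#' Round-trips losslessly through [read_cohort()]: numeric fields survive to
#' at least 1e-9 relative precision and subject ids (including non-ASCII)
#' are preserved byte-for-byte via UTF-8.
#'
#' @param m a validated `cohort_manifest`.
#' @param subjects_path,samples_path output paths.
#' @param format `"csv"` or `"tsv"` (default).
#' @export
write_cohort <- function(m, subjects_path, samples_path,
                         format = c("tsv", "csv")) {
  format <- match.arg(format)
  validate_manifest(m)
  .write_table(m$subjects, subjects_path, format)
  samples <- m$samples
  # proz is derived; keep it out of the file so the replicate columns stay
  # the single source of truth
  samples$proz <- NULL
  .write_table(samples, samples_path, format)
  invisible(m)
}

#' Tabulate a cohort by group, cancer type and stage
#'
#' @param m a `cohort_manifest`.
#' @return data frame with one row per (group, cancer_type, stage)
#'   combination present, a `n` count column, and an attribute `totals`
#'   giving counts per cancer type.  Counts partition the subject list.
#' @export
summarize_cohort <- function(m) {
  validate_manifest(m)
  s <- m$subjects
  if (nrow(s) == 0L) {
    out <- data.frame(group = character(), cancer_type = character(),
                      stage = character(), n = integer())
    attr(out, "totals") <- c(control = 0L, type1 = 0L, type2 = 0L)
    return(out)
  }
  agg <- stats::aggregate(list(n = seq_len(nrow(s))),
                          by = list(group = s$group,
                                    cancer_type = s$cancer_type,
                                    stage = s$stage),
                          FUN = length)
  agg <- agg[order(agg$cancer_type, agg$stage), , drop = FALSE]
  rownames(agg) <- NULL
  tot <- table(factor(s$cancer_type, levels = .cancer_levels))
  attr(agg, "totals") <- c(control = unname(tot[["none"]]),
                           type1 = unname(tot[["type1"]]),
                           type2 = unname(tot[["type2"]]))
  agg
}
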