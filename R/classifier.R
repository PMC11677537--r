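#' Dual-evidence METex14 classification
#'
#' RNA fusion reads spanning the MET exon13-exon15 junction are the primary
#' diagnostic evidence for MET exon 14 skipping; the assay calls a sample
#' positive at 120 or more fusion reads. Samples detected above the
#' retention floor (more than 20 reads) but below 120 sit in an
#' undetermined zone, where a filter-passing DNA variant in the exon 14
#' splice acceptor/donor windows rescues the diagnosis. Samples with no
#' retained fusion record but splice-window DNA evidence are DNA-only
#' positives, distinct from RNA-confirmed positives in every output.
#'
#' @name metex14_classifier
NULL

.categories <- c("RNA_POSITIVE", "DNA_RESCUED", "UNDETERMINED",
                 "DNA_ONLY_POSITIVE", "NEGATIVE")

#' Classifier thresholds
#'
#' @param rna_positive_threshold Fusion reads at or above which a sample is
#'   RNA-positive (inclusive; assay guidance phrases it as "at least 120").
#' @param rna_detect_threshold_exclusive Retention floor: fusion records
#'   with this many reads or fewer are treated as undetected (matches the
#'   RNA retention filter's "more than 20" rule).
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(rna_positive_threshold = 120,
                              rna_detect_threshold_exclusive = 20) {
  if (!(rna_positive_threshold > rna_detect_threshold_exclusive &&
        rna_detect_threshold_exclusive >= 0)) {
    .fail("need rna_positive_threshold > rna_detect_threshold_exclusive >= 0")
  }
  structure(list(rna_positive_threshold = rna_positive_threshold,
                 rna_detect_threshold_exclusive = rna_detect_threshold_exclusive),
            class = "classifier_config")
}

#' Classify one patient
#'
#' Decision table (with default thresholds): (a) reads >= 120 ->
#' `RNA_POSITIVE`; (b) 20 < reads < 120 with at least one splice-window DNA
#' variant -> `DNA_RESCUED`; (c) 20 < reads < 120 without one ->
#' `UNDETERMINED`; (d) no retained fusion record but splice-window DNA
#' evidence -> `DNA_ONLY_POSITIVE`; (e) otherwise `NEGATIVE`. A fusion
#' record at or below the retention floor is identical to no record.
#'
#' @param rna_reads Retained fusion read count; 0 or `NA` when the patient
#'   has no retained fusion record.
#' @param n_dna_splice_variants Number of filter-passing DNA variants
#'   overlapping the splice windows.
#' @param cfg A [classifier_config()].
#' @return List with `category`, `rna_reads`, `n_dna_splice_variants` and a
#'   `rationale` string naming the rule that fired.
#' @export
classify_metex14 <- function(rna_reads, n_dna_splice_variants,
                             cfg = classifier_config()) {
  if (is.na(rna_reads)) rna_reads <- 0
  if (rna_reads < 0 || n_dna_splice_variants < 0) {
    .fail("negative counts")
  }
  pos <- cfg$rna_positive_threshold
  det <- cfg$rna_detect_threshold_exclusive
  has_dna <- n_dna_splice_variants >= 1
  if (rna_reads >= pos) {
    category <- "RNA_POSITIVE"
    rationale <- sprintf("rna_reads %d >= positive threshold %d",
                         as.integer(rna_reads), as.integer(pos))
  } else if (rna_reads > det && has_dna) {
    category <- "DNA_RESCUED"
    rationale <- sprintf(
      "rna_reads %d in (%d, %d) with %d splice-window DNA variant(s)",
      as.integer(rna_reads), as.integer(det), as.integer(pos),
      as.integer(n_dna_splice_variants))
  } else if (rna_reads > det) {
    category <- "UNDETERMINED"
    rationale <- sprintf(
      "rna_reads %d in (%d, %d) without splice-window DNA evidence",
      as.integer(rna_reads), as.integer(det), as.integer(pos))
  } else if (has_dna) {
    category <- "DNA_ONLY_POSITIVE"
    rationale <- sprintf(
      "no retained fusion record; %d splice-window DNA variant(s)",
      as.integer(n_dna_splice_variants))
  } else {
    category <- "NEGATIVE"
    rationale <- "no retained fusion record and no splice-window DNA evidence"
  }
  list(category = factor(category, levels = .categories),
       rna_reads = as.integer(rna_reads),
       n_dna_splice_variants = as.integer(n_dna_splice_variants),
       rationale = rationale)
}

#' Classify a cohort
#'
#' Full pipeline step: applies the RNA retention filter to the fusion
#' table, the DNA retention filters plus splice-window annotation to the
#' variant table, and the decision table to every patient.
#'
#' @param patient_ids Character vector of all patients to call (patients
#'   without evidence are called `NEGATIVE`).
#' @param fusions Fusion `data.frame` (see [read_fusion_table()]). Only
#'   METex14-type records (5' exon 13, 3' exon 15) are used.
#' @param variants Variant `data.frame` (see [read_vcf_variants()]).
#' @param windows A [build_splice_windows()] result for exon 14.
#' @param filter_cfg A [filter_config()].
#' @param cfg A [classifier_config()].
#' @return `data.frame` with one row per patient: `patient_id`, `category`,
#'   `rna_reads`, `n_dna_splice_variants`, `dna_alt_coverage` (alt reads of
#'   the best splice-window variant, 0 when none), `rationale`.
#' @export
classify_cohort <- function(patient_ids, fusions, variants, windows,
                            filter_cfg = filter_config(),
                            cfg = classifier_config()) {
  fus <- fusions[fusions$five_prime_exon == 13 & fusions$three_prime_exon == 15, ,
                 drop = FALSE]
  fus <- apply_rna_filter(fus, filter_cfg)
  fus <- fus[fus$keep, , drop = FALSE]
  reads <- tapply(fus$read_count, fus$patient_id, max)

  dna <- variants
  if (nrow(dna)) {
    dna <- apply_dna_filters(dna, filter_cfg)
    dna <- dna[dna$keep, , drop = FALSE]
    dna <- annotate_splice_region(dna, windows)
    dna <- dna[dna$splice_region != "none", , drop = FALSE]
  }
  n_dna <- tapply(rep(1L, nrow(dna)), dna$patient_id, sum)
  cov <- tapply(dna$alt_reads, dna$patient_id, max)

  # vectorised application of the classify_metex14() decision table
  rr <- unname(reads[match(patient_ids, names(reads))])
  rr[is.na(rr)] <- 0L
  nd <- unname(n_dna[match(patient_ids, names(n_dna))])
  nd[is.na(nd)] <- 0L
  cv <- unname(cov[match(patient_ids, names(cov))])
  cv[is.na(cv)] <- 0
  if (any(rr < 0) || any(nd < 0)) .fail("negative counts")
  pos <- cfg$rna_positive_threshold
  det <- cfg$rna_detect_threshold_exclusive
  category <- ifelse(rr >= pos, "RNA_POSITIVE",
              ifelse(rr > det & nd >= 1, "DNA_RESCUED",
              ifelse(rr > det, "UNDETERMINED",
              ifelse(nd >= 1, "DNA_ONLY_POSITIVE", "NEGATIVE"))))
  rationale <- character(length(rr))
  rationale[category == "RNA_POSITIVE"] <- sprintf(
    "rna_reads %d >= positive threshold %d", rr[category == "RNA_POSITIVE"],
    as.integer(pos))
  rationale[category == "DNA_RESCUED"] <- sprintf(
    "rna_reads %d in (%d, %d) with %d splice-window DNA variant(s)",
    rr[category == "DNA_RESCUED"], as.integer(det), as.integer(pos),
    nd[category == "DNA_RESCUED"])
  rationale[category == "UNDETERMINED"] <- sprintf(
    "rna_reads %d in (%d, %d) without splice-window DNA evidence",
    rr[category == "UNDETERMINED"], as.integer(det), as.integer(pos))
  rationale[category == "DNA_ONLY_POSITIVE"] <- sprintf(
    "no retained fusion record; %d splice-window DNA variant(s)",
    nd[category == "DNA_ONLY_POSITIVE"])
  rationale[category == "NEGATIVE"] <-
    "no retained fusion record and no splice-window DNA evidence"
  data.frame(patient_id = patient_ids,
             category = factor(category, levels = .categories),
             rna_reads = as.integer(rr), n_dna_splice_variants = as.integer(nd),
             dna_alt_coverage = cv, rationale = rationale,
             stringsAsFactors = FALSE)
}

#' Pearson correlation with zero-imputation for undetected DNA
#'
#' Sample Pearson product-moment correlation between RNA fusion reads and
#' DNA coverage, where `NA` coverage means the DNA variant was not detected
#' and is imputed as 0 before the correlation. The p-value is the two-sided
#' value from the t transform with n-2 degrees of freedom.
#'
#' @param rna_reads Numeric vector.
#' @param dna_coverage Numeric vector, `NA` = not detected (imputed as 0).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_with_zero_imputation <- function(rna_reads, dna_coverage) {
  if (length(rna_reads) != length(dna_coverage)) .fail("length mismatch")
  y <- ifelse(is.na(dna_coverage), 0, dna_coverage)
  x <- rna_reads
  if (length(x) < 3) {
    .fail("need at least 3 pairs", "metexdx_undefined_correlation")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    .fail("zero variance: correlation undefined",
          "metexdx_undefined_correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' RNA/DNA concordance summary
#'
#' Over the fusion-detected patients of a classified cohort: the Pearson
#' correlation (zero-imputed DNA coverage) for all detected patients and
#' for the low-read subgroup, the fraction of RNA-positive patients with no
#' splice-window DNA variant, and the fraction of low-read patients rescued
#' by DNA. DNA coverage is the `dna_alt_coverage` column (alt-supporting
#' reads of the best splice-window variant; documented, configurable
#' upstream).
#'
#' @param calls [classify_cohort()] output.
#' @param lowread_denominator Denominator for the rescued fraction. Default
#'   `NULL` uses the number of low-read patients; a cohort manifest may pin
#'   a different reporting denominator.
#' @return List of class `concordance_stats`.
#' @export
concordance_summary <- function(calls, lowread_denominator = NULL) {
  detected <- calls[calls$category %in%
                      c("RNA_POSITIVE", "DNA_RESCUED", "UNDETERMINED"), ,
                    drop = FALSE]
  lowread <- detected[detected$category %in% c("DNA_RESCUED", "UNDETERMINED"), ,
                      drop = FALSE]
  rna_pos <- detected[detected$category == "RNA_POSITIVE", , drop = FALSE]
  all_ct <- pearson_with_zero_imputation(detected$rna_reads,
                                         detected$dna_alt_coverage)
  low_ct <- pearson_with_zero_imputation(lowread$rna_reads,
                                         lowread$dna_alt_coverage)
  denom <- lowread_denominator %||% nrow(lowread)
  structure(list(
    pearson_r_all = all_ct$r, p_value_all = signif(all_ct$p, 3),
    pearson_r_lowread = low_ct$r, p_value_lowread = signif(low_ct$p, 3),
    frac_rna_pos_dna_negative =
      if (nrow(rna_pos)) mean(rna_pos$n_dna_splice_variants == 0) else NA_real_,
    frac_lowread_dna_rescued = sum(lowread$category == "DNA_RESCUED") / denom,
    n_rna_detected = nrow(detected),
    n_rna_positive = nrow(rna_pos),
    n_undetermined_or_rescued = nrow(lowread),
    lowread_denominator = denom
  ), class = "concordance_stats")
}

#' @export
print.concordance_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<concordance_stats> detected %d (positive %d, low-read %d)\n",
           "  r(all) = %.3f (p = %.3g); r(low-read) = %.3f (p = %.3g)\n",
           "  RNA-positive DNA-negative: %.1f%%; low-read DNA-rescued: ",
           "%.1f%% (denominator %d)\n"),
    x$n_rna_detected, x$n_rna_positive, x$n_undetermined_or_rescued,
    x$pearson_r_all, x$p_value_all, x$pearson_r_lowread, x$p_value_lowread,
    100 * x$frac_rna_pos_dna_negative, 100 * x$frac_lowread_dna_rescued,
    x$lowread_denominator))
  invisible(x)
}

#' Write per-patient calls and concordance stats
#'
#' @param calls [classify_cohort()] output.
#' @param stats [concordance_summary()] output (optional).
#' @param dir Output directory.
#' @param config_note Configuration fingerprint recorded in the outputs.
#' @return Invisibly, the written paths.
#' @export
write_classifier_output <- function(calls, stats = NULL, dir,
                                    config_note = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- write_metexdx_tsv(calls, file.path(dir, "metex14_calls.tsv"),
                          header_note = config_note)
  p2 <- file.path(dir, "metex14_calls.json")
  jsonlite::write_json(
    c(list(config = config_note), list(calls = calls)), p2,
    auto_unbox = TRUE, digits = NA)
  paths <- c(p1, p2)
  if (!is.null(stats)) {
    p3 <- file.path(dir, "concordance.json")
    jsonlite::write_json(c(list(config = config_note), unclass(stats)), p3,
                         auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p3)
  }
  invisible(paths)
}
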