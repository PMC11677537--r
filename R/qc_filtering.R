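#' Sample QC gates and variant-retention filters
#'
#' Sample-level QC reflects a targeted amplicon assay run on FFPE biopsies:
#' a library passes when it reaches at least 240 median reads per amplicon,
#' at least 60% aligned reads (DNA), at least 20,000 correctly mapped RNA
#' reads, and at least 3 of 5 RNA expression-control amplicons. Variant
#' retention applies minimum allele frequency (5% SNV / 7% indel), minimum
#' 10 alt-supporting reads, minimum 50x site depth and minimum Phred-scaled
#' variant score (6 SNV / 20 indel); RNA fusion records are retained only
#' with strictly more than 20 supporting reads. All "minimum"-phrased
#' thresholds are inclusive; the fusion-read rule is exclusive.
#'
#' @name qc_filtering
NULL

#' Variant/fusion retention thresholds
#'
#' @param min_af_snv,min_af_indel Minimum allele frequency (inclusive).
#' @param min_alt_reads Minimum reads supporting the alternate allele
#'   (inclusive).
#' @param min_site_depth Minimum total depth at the variant site (inclusive).
#' @param min_phred_snv,min_phred_indel Minimum Phred-scaled variant score
#'   (inclusive).
#' @param min_fusion_reads_exclusive Fusion records are kept only when
#'   `read_count` is strictly greater than this.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_af_snv = 0.05, min_af_indel = 0.07,
                          min_alt_reads = 10, min_site_depth = 50,
                          min_phred_snv = 6, min_phred_indel = 20,
                          min_fusion_reads_exclusive = 20) {
  v <- c(min_af_snv, min_af_indel, min_alt_reads, min_site_depth,
         min_phred_snv, min_phred_indel, min_fusion_reads_exclusive)
  if (any(!is.finite(v)) || any(v < 0)) .fail("thresholds must be >= 0")
  structure(as.list(environment()), class = "filter_config")
}

#' Sample-level QC decision
#'
#' @param median_reads_per_amplicon,pct_aligned_reads,rna_mapped_reads,expression_controls_detected
#'   The four QC metrics for one library pair. `pct_aligned_reads` on the
#'   0-100 scale; `expression_controls_detected` in 0..5. A missing (`NA`)
#'   metric fails its gate with reason `"missing"`.
#' @param thresholds Named list of gate thresholds (defaults as documented).
#' @return List with `pass` (logical) and `failed` (character vector of
#'   failed gate names, empty when passing).
#' @export
sample_qc_pass <- function(median_reads_per_amplicon, pct_aligned_reads,
                           rna_mapped_reads, expression_controls_detected,
                           thresholds = list(median_reads_per_amplicon = 240,
                                             pct_aligned_reads = 60,
                                             rna_mapped_reads = 20000,
                                             expression_controls_detected = 3)) {
  vals <- list(median_reads_per_amplicon = median_reads_per_amplicon,
               pct_aligned_reads = pct_aligned_reads,
               rna_mapped_reads = rna_mapped_reads,
               expression_controls_detected = expression_controls_detected)
  failed <- character(0)
  for (g in names(vals)) {
    v <- vals[[g]]
    if (is.null(v) || length(v) != 1L || is.na(v)) {
      failed <- c(failed, paste0(g, ":missing"))
    } else if (v < thresholds[[g]]) {
      failed <- c(failed, g)
    }
  }
  list(pass = length(failed) == 0L, failed = failed)
}

#' Apply the QC gates to a metrics table
#'
#' @param qc `data.frame` with columns `patient_id`,
#'   `median_reads_per_amplicon`, `pct_aligned_reads`, `rna_mapped_reads`,
#'   `expression_controls_detected`.
#' @inheritParams sample_qc_pass
#' @return The input with logical `qc_pass` and character `qc_failed_gates`
#'   columns.
#' @export
apply_sample_qc <- function(qc, thresholds = NULL) {
  stopifnot(is.data.frame(qc))
  args <- list()
  if (!is.null(thresholds)) args$thresholds <- thresholds
  res <- lapply(seq_len(nrow(qc)), function(i) {
    do.call(sample_qc_pass, c(list(
      qc$median_reads_per_amplicon[i], qc$pct_aligned_reads[i],
      qc$rna_mapped_reads[i], qc$expression_controls_detected[i]), args))
  })
  qc$qc_pass <- vapply(res, `[[`, logical(1), "pass")
  qc$qc_failed_gates <- vapply(res, function(r) paste(r$failed, collapse = ";"),
                               character(1))
  qc
}

#' SNV or indel?
#'
#' A variant is an SNV iff both alleles have length 1; anything else
#' (insertion, deletion, MNV) is treated as `INDEL` for thresholding.
#'
#' @param ref,alt Allele strings (vectorised).
#' @return Character vector of `"SNV"` / `"INDEL"`.
#' @export
classify_variant_type <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt))) .fail("empty allele string")
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "INDEL")
}

#' DNA variant retention decision
#'
#' Vectorised over a variant table. A variant is kept iff its allele
#' frequency, alt-read count, site depth and Phred score all reach the
#' class-specific minima (inclusive). Failing variants are never deleted:
#' the returned table carries `keep` plus a semicolon-joined `drop_reasons`
#' audit column. When both `allele_frequency` and the two depths are
#' present, an `af_inconsistent` flag marks records where
#' `|AF - alt_reads/site_depth| > 0.01` (flagged, not dropped).
#'
#' @param variants `data.frame` with columns `ref`, `alt`,
#'   `allele_frequency`, `site_depth`, `alt_reads`, `quality_phred`.
#' @param cfg A [filter_config()].
#' @param hotspot Optional allow-list `data.frame` with columns `chromosome`
#'   and `pos`; when supplied, variants at other positions are dropped with
#'   reason `"hotspot"`. When `NULL` (default) all positions are eligible.
#' @return The input plus `variant_class`, `keep`, `drop_reasons`,
#'   `af_inconsistent` columns.
#' @export
apply_dna_filters <- function(variants, cfg = filter_config(), hotspot = NULL) {
  stopifnot(is.data.frame(variants), inherits(cfg, "filter_config"))
  n <- nrow(variants)
  if (n == 0) {
    variants$variant_class <- character(0)
    variants$keep <- logical(0)
    variants$drop_reasons <- character(0)
    variants$af_inconsistent <- logical(0)
    return(variants)
  }
  if (any(variants$alt_reads > variants$site_depth, na.rm = TRUE)) {
    .fail("alt_reads exceeds site_depth")
  }
  if (any(variants$allele_frequency < 0 | variants$allele_frequency > 1,
          na.rm = TRUE)) {
    .fail("allele_frequency outside [0, 1]")
  }
  cls <- classify_variant_type(variants$ref, variants$alt)
  min_af <- ifelse(cls == "SNV", cfg$min_af_snv, cfg$min_af_indel)
  min_ph <- ifelse(cls == "SNV", cfg$min_phred_snv, cfg$min_phred_indel)
  reasons <- vector("list", n)
  add <- function(reasons, bad, label) {
    for (i in which(bad)) reasons[[i]] <- c(reasons[[i]], label)
    reasons
  }
  reasons <- add(reasons, variants$allele_frequency < min_af, "allele_frequency")
  reasons <- add(reasons, variants$alt_reads < cfg$min_alt_reads, "alt_reads")
  reasons <- add(reasons, variants$site_depth < cfg$min_site_depth, "site_depth")
  reasons <- add(reasons, variants$quality_phred < min_ph, "quality")
  if (!is.null(hotspot)) {
    key <- paste(variants$chromosome, variants$pos)
    reasons <- add(reasons, !key %in% paste(hotspot$chromosome, hotspot$pos),
                   "hotspot")
  }
  variants$variant_class <- cls
  variants$keep <- vapply(reasons, function(r) is.null(r), logical(1))
  variants$drop_reasons <- vapply(reasons, function(r)
    paste(r, collapse = ";"), character(1))
  af_implied <- ifelse(variants$site_depth > 0,
                       variants$alt_reads / variants$site_depth, NA_real_)
  variants$af_inconsistent <- !is.na(af_implied) &
    abs(variants$allele_frequency - af_implied) > 0.01
  variants
}

#' Single-variant retention decision
#'
#' Scalar convenience wrapper over [apply_dna_filters()].
#'
#' @inheritParams apply_dna_filters
#' @param ref,alt,allele_frequency,site_depth,alt_reads,quality_phred One
#'   variant's fields.
#' @return List with `keep` (logical) and `failed` (character vector of
#'   failed rule names).
#' @export
passes_dna_filters <- function(ref, alt, allele_frequency, site_depth,
                               alt_reads, quality_phred,
                               cfg = filter_config()) {
  r <- apply_dna_filters(data.frame(
    ref = ref, alt = alt, allele_frequency = allele_frequency,
    site_depth = site_depth, alt_reads = alt_reads,
    quality_phred = quality_phred), cfg)
  list(keep = r$keep,
       failed = if (nzchar(r$drop_reasons)) strsplit(r$drop_reasons, ";")[[1]]
                else character(0))
}

#' RNA fusion retention decision
#'
#' Keeps fusion records with strictly more than
#' `cfg$min_fusion_reads_exclusive` supporting reads (default: more than 20).
#'
#' @param read_count Integer vector of fusion-supporting read counts.
#' @param cfg A [filter_config()].
#' @return Logical vector, `TRUE` = keep.
#' @export
passes_rna_filter <- function(read_count, cfg = filter_config()) {
  if (any(read_count < 0)) .fail("negative read count")
  read_count > cfg$min_fusion_reads_exclusive
}

#' Apply the RNA fusion filter to a fusion table
#'
#' @param fusions `data.frame` with a `read_count` column.
#' @param cfg A [filter_config()].
#' @return The input plus a logical `keep` column.
#' @export
apply_rna_filter <- function(fusions, cfg = filter_config()) {
  stopifnot(is.data.frame(fusions))
  fusions$keep <- if (nrow(fusions)) passes_rna_filter(fusions$read_count, cfg)
                  else logical(0)
  fusions
}
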