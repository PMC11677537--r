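#' Cohort-level prevalence and comparison reporting
#'
#' Per-gene prevalence over a cohort (a patient with several variants in a
#' gene counts once), a two-cohort prevalence comparison by two-sided
#' Fisher exact test with conventional star labels, the clinical
#' significance breakdown, and an oncoplot-style patient x gene 0/1
#' matrix. External reference-cohort prevalences enter as plain (count, n)
#' configuration numbers.
#'
#' @name cohort_report
NULL

#' Per-gene prevalence
#'
#' @param patient_genes `data.frame` with columns `patient_id`, `gene`.
#' @param n_cohort Cohort size (> 0).
#' @param genes Genes to report; default: all present in `patient_genes`.
#' @return `data.frame` with `gene`, `n_patients_with_variant`, `n_cohort`,
#'   `prevalence`.
#' @export
gene_prevalence <- function(patient_genes, n_cohort, genes = NULL) {
  if (!.is_count(n_cohort) || n_cohort <= 0) .fail("n_cohort must be > 0")
  pg <- unique(patient_genes[, c("patient_id", "gene")])
  genes <- genes %||% sort(unique(pg$gene))
  counts <- vapply(genes, function(g) sum(pg$gene == g), integer(1))
  data.frame(gene = genes, n_patients_with_variant = unname(counts),
             n_cohort = n_cohort, prevalence = unname(counts) / n_cohort,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance star label
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, else `ns`.
#'
#' @param p p-value in [0, 1].
#' @return Character label.
#' @export
significance_label <- function(p) {
  if (is.na(p) || p < 0 || p > 1) .fail("p must be in [0, 1]")
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*"
  else "ns"
}

#' Two-cohort prevalence comparison
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `rbind(c(count_a, n_a - count_a), c(count_b, n_b - count_b))`. The test
#' choice (exact, two-sided) is stamped into the result.
#'
#' @param gene Gene label for the output row.
#' @param count_a,n_a Affected count and cohort size, cohort A.
#' @param count_b,n_b Affected count and cohort size, cohort B.
#' @return List with `gene`, `a`, `b`, `p_value`, `significance_label`,
#'   `test`.
#' @export
compare_prevalence <- function(gene, count_a, n_a, count_b, n_b) {
  if (n_a <= 0 || n_b <= 0) .fail("degenerate table: cohort size must be > 0")
  if (count_a > n_a || count_b > n_b) .fail("count exceeds cohort size")
  tab <- rbind(c(count_a, n_a - count_a), c(count_b, n_b - count_b))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  p <- min(p, 1)
  list(gene = gene, a = c(count = count_a, n = n_a),
       b = c(count = count_b, n = n_b), p_value = p,
       significance_label = significance_label(p),
       test = "two-sided Fisher exact")
}

#' Compare a cohort prevalence table against a reference config
#'
#' @param prevalence [gene_prevalence()] output for the study cohort.
#' @param reference List with `cohort_size` (or `n`) and named `genes`
#'   counts, as read from a YAML reference file
#'   (e.g. `system.file("extdata", "reference_cohort_prevalence.yaml",
#'   package = "metexdx")`).
#' @return `data.frame`, one row per shared gene, with both prevalences,
#'   `p_value` and `significance_label`.
#' @export
compare_prevalence_table <- function(prevalence, reference) {
  n_ref <- reference$cohort_size %||% reference$n
  if (is.null(n_ref)) .fail("reference needs a cohort_size")
  shared <- intersect(prevalence$gene, names(reference$genes))
  rows <- lapply(shared, function(g) {
    a <- prevalence[prevalence$gene == g, ]
    cmp <- compare_prevalence(g, a$n_patients_with_variant, a$n_cohort,
                              reference$genes[[g]], n_ref)
    data.frame(gene = g, count_a = a$n_patients_with_variant,
               n_a = a$n_cohort, prevalence_a = a$prevalence,
               count_b = reference$genes[[g]], n_b = n_ref,
               prevalence_b = reference$genes[[g]] / n_ref,
               p_value = cmp$p_value,
               significance_label = cmp$significance_label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clinical-significance breakdown
#'
#' Counts and percentages per clinical significance class. The denominator
#' is an explicit, required parameter: published breakdowns are ambiguous
#' about whether they are per-variant or per-patient, so the caller states
#' which denominator the table is over.
#'
#' @param classes Character vector of class labels, one per counted unit
#'   (variant or patient), from `actionable`, `likely_actionable`, `VUS`,
#'   `benign_other`.
#' @param denominator Positive denominator for the percentages.
#' @return `data.frame` with `class`, `count`, `percentage`.
#' @export
clinical_significance_breakdown <- function(classes, denominator) {
  allowed <- c("actionable", "likely_actionable", "VUS", "benign_other")
  bad <- setdiff(unique(classes), allowed)
  if (length(bad)) .fail(paste("unknown class label:", paste(bad, collapse = ", ")))
  if (!.is_count(denominator) || denominator <= 0) {
    .fail("denominator must be > 0")
  }
  counts <- vapply(allowed, function(cl) sum(classes == cl), integer(1))
  data.frame(class = allowed, count = unname(counts),
             percentage = 100 * unname(counts) / denominator,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Oncoplot-style 0/1 patient x gene matrix
#'
#' @param patient_genes `data.frame` with `patient_id`, `gene`.
#' @param patient_ids All cohort patients (rows); default: those present.
#' @param genes Genes (columns); default: those present.
#' @return Integer matrix, 1 = patient carries a variant in the gene.
#' @export
oncoplot_matrix <- function(patient_genes, patient_ids = NULL, genes = NULL) {
  pg <- unique(patient_genes[, c("patient_id", "gene")])
  patient_ids <- patient_ids %||% sort(unique(pg$patient_id))
  genes <- genes %||% sort(unique(pg$gene))
  m <- matrix(0L, nrow = length(patient_ids), ncol = length(genes),
              dimnames = list(patient_ids, genes))
  keep <- pg$patient_id %in% patient_ids & pg$gene %in% genes
  pg <- pg[keep, , drop = FALSE]
  m[cbind(match(pg$patient_id, patient_ids), match(pg$gene, genes))] <- 1L
  m
}

#' Write the cohort report bundle
#'
#' Prevalence TSV, two-cohort comparison TSV, significance JSON and the
#' oncoplot matrix TSV.
#'
#' @param prevalence [gene_prevalence()] output.
#' @param comparison [compare_prevalence_table()] output (optional).
#' @param breakdown [clinical_significance_breakdown()] output (optional).
#' @param onco [oncoplot_matrix()] output (optional).
#' @param dir Output directory.
#' @param config_note Configuration fingerprint for headers.
#' @return Invisibly, the written paths.
#' @export
write_cohort_report <- function(prevalence, comparison = NULL,
                                breakdown = NULL, onco = NULL, dir,
                                config_note = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_metexdx_tsv(prevalence, file.path(dir, "prevalence.tsv"),
                             header_note = config_note)
  if (!is.null(comparison)) {
    paths <- c(paths, write_metexdx_tsv(
      comparison, file.path(dir, "two_cohort_comparison.tsv"),
      header_note = paste(config_note, "test=two-sided Fisher exact")))
    sig <- file.path(dir, "significance.json")
    jsonlite::write_json(
      list(test = "two-sided Fisher exact", config = config_note,
           genes = comparison[, c("gene", "p_value", "significance_label")]),
      sig, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, sig)
  }
  if (!is.null(breakdown)) {
    paths <- c(paths, write_metexdx_tsv(
      breakdown, file.path(dir, "clinical_significance.tsv"),
      header_note = config_note))
  }
  if (!is.null(onco)) {
    om <- data.frame(patient_id = rownames(onco), onco, check.names = FALSE)
    paths <- c(paths, write_metexdx_tsv(
      om, file.path(dir, "oncoplot_matrix.tsv"), header_note = config_note))
  }
  invisible(paths)
}
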