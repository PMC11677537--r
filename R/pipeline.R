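#' End-to-end cohort analysis
#'
#' Runs the full analysis on a `metex_cohort` (simulated, fixture, or read
#' from disk): QC gating, variant/fusion filtering, splice-window
#' annotation, METex14 classification, RNA/DNA concordance, VUS consensus
#' triage, the co-occurring actionable variant screen, and the prevalence
#' report inputs.
#'
#' @param cohort A `metex_cohort`.
#' @param gene_model As returned by [met_gene_model()] /
#'   [read_gene_model()].
#' @param filter_cfg A [filter_config()].
#' @param classifier_cfg A [classifier_config()].
#' @param sets Actionability gene sets ([read_actionable_genes()]).
#' @param domains Protein domain table ([read_domain_table()]).
#' @param cadd_threshold Strict CADD driver cutoff.
#' @return List with `calls` ([classify_cohort()] output), `concordance`
#'   ([concordance_summary()], using the manifest's low-read reporting
#'   denominator when present), `triage` ([triage_vus()] output), `screen`
#'   ([screen_cohort()] output for all patients), `patient_genes`,
#'   `prevalence` ([gene_prevalence()] over the cohort), `windows` and the
#'   configurations used.
#' @export
analyze_cohort <- function(cohort,
                           gene_model = met_gene_model(),
                           filter_cfg = filter_config(),
                           classifier_cfg = classifier_config(),
                           sets = read_actionable_genes(),
                           domains = read_domain_table(),
                           cadd_threshold = 25) {
  windows <- build_splice_windows(gene_model$model, 14, gene_model$windows)
  calls <- classify_cohort(cohort$patients$patient_id, cohort$fusions,
                           cohort$variants, windows,
                           filter_cfg = filter_cfg, cfg = classifier_cfg)
  lden <- cohort$manifest$lowread_denominator %||% NULL
  concordance <- concordance_summary(calls, lowread_denominator = lden)
  triage <- triage_vus(cohort$annotations, cadd_threshold = cadd_threshold,
                       domains = domains)
  pg <- cohort_patient_genes(cohort)
  screen <- screen_cohort(pg, sets)
  prevalence <- gene_prevalence(pg, n_cohort = nrow(cohort$patients))
  list(calls = calls, concordance = concordance, triage = triage,
       screen = screen, patient_genes = pg, prevalence = prevalence,
       windows = windows,
       config = list(filter = filter_cfg, classifier = classifier_cfg,
                     cadd_threshold = cadd_threshold))
}

#' Carriers of consensus-driver VUSs
#'
#' Patients carrying a given set of consensus-predicted driver protein
#' changes, joined with the co-occurrence screen.
#'
#' @param cohort A `metex_cohort`.
#' @param analysis [analyze_cohort()] output.
#' @param variant_ids Protein changes of interest; default: all
#'   consensus-predicted drivers.
#' @return `data.frame` with `patient_id`, `protein_change`,
#'   `has_other_any`, `has_other_lung`.
#' @export
driver_vus_carriers <- function(cohort, analysis, variant_ids = NULL) {
  drv <- analysis$triage$variant_id[analysis$triage$is_predicted_driver]
  variant_ids <- variant_ids %||% drv
  keep <- intersect(variant_ids, drv)
  v <- cohort$variants
  carriers <- unique(v[!is.na(v$protein_change) &
                         v$protein_change %in% keep,
                       c("patient_id", "protein_change")])
  out <- merge(carriers, analysis$screen, by = "patient_id", all.x = TRUE)
  out[order(out$patient_id), , drop = FALSE]
}
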