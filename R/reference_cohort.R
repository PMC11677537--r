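#' Deterministic reference cohort
#'
#' A fixed synthetic cohort used as the package's end-to-end fixture. Its
#' aggregate composition encodes the published figures the default
#' thresholds emulate: 1560 patients, 123 MET-variant carriers (8%
#' prevalence), 72 with retained exon13-exon15 fusion records spanning 21
#' to 67,000 reads, 35 at or above the 120-read positive threshold, 37
#' below it, exactly 7 low-read patients rescued by a filter-passing
#' splice-window DNA variant, a designated 35-patient low-read reporting
#' denominator (20 of whom carry no other actionable variant, 25 no other
#' lung-actionable one), 11 T992I and 6 H1094Y consensus-driver VUS
#' carriers (7 of the 17 with no other actionable variant), and 16 of the
#' 35 RNA-positives with DNA splice evidence (so 54.3% are DNA-negative,
#' including patients at 3170, 9487 and 12,301 reads). One rescued patient
#' sits at 46 reads, the read count of a published case with an immediate
#' MET-inhibitor response. Per-patient values are synthetic: only these
#' aggregates are meaningful.
#'
#' Construction is pure arithmetic (no RNG): re-running always yields a
#' byte-identical cohort.
#'
#' @return A `metex_cohort` (see [simulate_cohort()]); `manifest` records
#'   every designed count, the 35-patient low-read denominator and its
#'   patient ids.
#' @export
build_reference_cohort <- function() {
  gm <- met_gene_model()
  windows <- build_splice_windows(gm$model, 14, gm$windows)
  tmpl <- .splice_variant_templates(windows)
  ids <- sprintf("P%04d", 1:1560)
  met_ids <- ids[1:123]

  ## --- fusion reads ---------------------------------------------------
  specials <- c(3170, 9487, 12301)                 # DNA-negative high-read
  reads_pos <- sort(c(round(exp(seq(log(125), log(67000),
                                    length.out = 32))), specials))
  pos_ids <- ids[1:35]                              # RNA_POSITIVE
  rescued_ids <- ids[36:42]                         # DNA_RESCUED
  reads_rescued <- c(46, 35, 52, 64, 78, 90, 110)
  undet_ids <- ids[43:72]                           # UNDETERMINED
  reads_undet <- round(seq(21, 119, length.out = 30))
  lowread_denom_ids <- ids[36:70]                   # reporting denominator

  fusions <- data.frame(
    patient_id = c(pos_ids, rescued_ids, undet_ids, ids[90], ids[91]),
    fusion_id = "MET-MET.M13M15",
    five_prime_exon = 13L, three_prime_exon = 15L,
    read_count = c(reads_pos, reads_rescued, reads_undet, 15L, 20L),
    stringsAsFactors = FALSE)          # last two fall below the RNA filter

  ## --- DNA splice-window variants --------------------------------------
  splice_row <- function(pid, kind, af, alt) {
    t <- tmpl[tmpl$kind == kind, ]
    depth <- max(round(alt / af), alt)
    data.frame(
      patient_id = pid, chromosome = t$chromosome, pos = t$pos,
      ref = t$ref, alt = t$alt,
      allele_frequency = round(alt / depth, 4),
      site_depth = depth, alt_reads = alt,
      quality_phred = if (nchar(t$ref) != nchar(t$alt)) 40 else 35,
      gene = "MET", protein_change = NA_character_, stringsAsFactors = FALSE)
  }
  # 16 DNA-positive RNA-positives: the highest-read patients that are not
  # the designated DNA-negative specials; alt coverage grows with reads
  ord <- order(reads_pos, decreasing = TRUE)
  dna_pos_idx <- setdiff(ord[!reads_pos[ord] %in% specials], integer(0))[1:16]
  kinds <- rep(c("donor_snv", "donor_snv", "donor_del", "acceptor_snv"), 4)
  variants <- list()
  for (k in seq_along(dna_pos_idx)) {
    i <- dna_pos_idx[k]
    alt <- round(20 + 15 * log10(reads_pos[i]))
    variants[[length(variants) + 1L]] <-
      splice_row(pos_ids[i], kinds[k], af = 0.15 + 0.01 * k, alt = alt)
  }
  # 7 rescued low-read patients (two germline-like AFs near 0.5);
  # alt coverage loosely tracks the read count
  resc_kind <- c("donor_snv", "donor_snv", "donor_del", "acceptor_snv",
                 "donor_snv", "donor_del", "acceptor_snv")
  resc_af <- c(0.12, 0.09, 0.18, 0.22, 0.31, 0.48, 0.51)
  resc_alt <- round(8 + 0.2 * reads_rescued)
  for (k in 1:7) {
    variants[[length(variants) + 1L]] <-
      splice_row(rescued_ids[k], resc_kind[k], resc_af[k], resc_alt[k])
  }

  ## --- MET VUS carriers -------------------------------------------------
  catalog <- .vus_catalog()
  vus_row <- function(pid, vid, i) {
    cv <- catalog[catalog$variant_id == vid, ]
    af <- 0.18 + 0.01 * (i %% 12)
    alt <- 40 + 2 * (i %% 9)
    depth <- round(alt / af)
    data.frame(
      patient_id = pid, chromosome = cv$chromosome, pos = cv$pos,
      ref = cv$ref, alt = cv$alt, allele_frequency = round(alt / depth, 4),
      site_depth = depth, alt_reads = alt, quality_phred = 35,
      gene = "MET", protein_change = cv$protein_change,
      stringsAsFactors = FALSE)
  }
  t992i_ids <- ids[73:83]                           # 11 carriers
  h1094y_ids <- ids[84:89]                          # 6 carriers
  for (i in seq_along(t992i_ids)) {
    variants[[length(variants) + 1L]] <- vus_row(t992i_ids[i], "T992I", i)
  }
  for (i in seq_along(h1094y_ids)) {
    variants[[length(variants) + 1L]] <- vus_row(h1094y_ids[i], "H1094Y", i)
  }
  # remaining MET carriers cycle through the rest of the VUS catalog
  other_met <- ids[90:123]
  other_vus <- setdiff(catalog$variant_id, c("T992I", "H1094Y"))
  for (i in seq_along(other_met)) {
    variants[[length(variants) + 1L]] <-
      vus_row(other_met[i], other_vus[(i - 1) %% length(other_vus) + 1], i)
  }

  ## --- co-occurring variants in other genes ----------------------------
  loci <- .other_gene_loci()
  other_row <- function(pid, gene) {
    lg <- loci[loci$gene == gene, ]
    data.frame(
      patient_id = pid, chromosome = lg$chromosome, pos = lg$pos,
      ref = lg$ref, alt = lg$alt, allele_frequency = 0.25,
      site_depth = 160, alt_reads = 40, quality_phred = 35,
      gene = gene, protein_change = NA_character_, stringsAsFactors = FALSE)
  }
  extras <- c(
    setNames(rep("EGFR", 4), ids[56:59]), setNames(rep("KRAS", 4), ids[60:63]),
    setNames("ALK", ids[64]), setNames("ERBB2", ids[65]),
    setNames("ESR1", ids[66]), setNames("ERBB4", ids[67]),
    setNames(rep("PIK3CA", 3), ids[68:70]),
    setNames("EGFR", ids[71]),
    setNames(rep("EGFR", 2), ids[80:81]), setNames(rep("KRAS", 2), ids[82:83]),
    setNames("BRAF", ids[84]), setNames("ALK", ids[85]),
    setNames(rep("PIK3CA", 2), ids[86:87]),
    setNames("IDH2", ids[88]), setNames("MTOR", ids[89]))
  for (pid in names(extras)) {
    variants[[length(variants) + 1L]] <- other_row(pid, extras[[pid]])
  }
  # fill non-MET patients so cohort prevalences sit at realistic levels
  fill <- list(KRAS = 306, EGFR = 274, ALK = 138, ERBB2 = 124, BRAF = 46,
               ROS1 = 31, RET = 31)
  nxt <- 124
  for (g in names(fill)) {
    take <- ids[nxt:(nxt + fill[[g]] - 1)]
    nxt <- nxt + fill[[g]]
    for (pid in take) {
      variants[[length(variants) + 1L]] <- other_row(pid, g)
    }
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  ## --- QC, clinical, classes -------------------------------------------
  n <- length(ids)
  i <- seq_len(n)
  qc <- data.frame(
    patient_id = ids,
    median_reads_per_amplicon = 280 + (i %% 300),
    pct_aligned_reads = 80 + (i %% 15),
    rna_mapped_reads = 40000 + 500L * i,
    expression_controls_detected = 3L + (i %% 3L),
    stringsAsFactors = FALSE)

  rep_counts <- function(values, counts, total) {
    out <- rep(values, counts)
    c(out, values[1 + (seq_len(total - length(out)) %% length(values))])
  }
  sex <- country <- stage <- smoking <- character(n)
  sex[1:123] <- rep_counts(c("women", "men"), c(66, 57), 123)
  country[1:123] <- rep_counts(c("Chile", "Brazil", "Peru"), c(88, 25, 10), 123)
  stage[1:123] <- rep_counts(c("IV", "III", "II", "I"), c(77, 25, 13, 8), 123)
  smoking[1:123] <- rep_counts(c("never", "former", "current"),
                               c(38, 64, 21), 123)
  j <- 124:n
  sex[j] <- c("women", "men")[1 + (j %% 2)]
  country[j] <- c("Chile", "Brazil", "Peru")[1 + (j %% 3)]
  stage[j] <- c("IV", "III", "II", "I")[1 + (j %% 4)]
  smoking[j] <- c("never", "former", "current")[1 + (j %% 3)]
  clin_class <- rep(NA_character_, n)
  clin_class[1:19] <- "actionable"
  clin_class[20:31] <- "likely_actionable"
  clin_class[32:123] <- "VUS"
  patients <- data.frame(
    patient_id = ids, met_carrier = ids %in% met_ids,
    clinical_significance = clin_class,
    sex = sex, country = country, stage = stage, smoking = smoking,
    stringsAsFactors = FALSE)

  manifest <- list(
    generator = "build_reference_cohort",
    seed = NA, config_hash = rlang::hash("reference-cohort-v1"),
    n_patients = n, n_met = 123, n_fusion_detected = 72,
    n_rna_positive = 35, n_lowread = 37, n_dna_rescued = 7,
    lowread_denominator = 35, lowread_denominator_ids = lowread_denom_ids,
    n_rna_positive_dna_positive = 16,
    n_t992i = 11, n_h1094y = 6,
    n_carriers_no_other_actionable = 7,
    n_lowread_no_other_actionable = 20,
    n_lowread_no_other_lung_actionable = 25,
    read_range = c(21, 67000))
  structure(list(patients = patients, variants = variants, fusions = fusions,
                 qc = qc,
                 annotations = catalog[, c("variant_id", "gene",
                                           "protein_change", "sift",
                                           "polyphen2", "mutation_taster",
                                           "cadd_phred", "cgi",
                                           "clinical_significance")],
                 manifest = manifest),
            class = "metex_cohort")
}
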