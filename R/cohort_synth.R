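#' Synthetic METex14 cohorts
#'
#' Generates cohorts with the statistical structure the diagnostic analysis
#' assumes: a MET-variant prevalence around 8%, fusion read counts spanning
#' roughly 20 to 67,000 (log-normal, three orders of magnitude), DNA
#' alt-coverage correlated with fusion reads on the log scale through a
#' Gaussian copula, DNA dropout among fusion-detected patients, allele
#' frequencies from a two-component Beta mixture with a germline-like mode
#' near 0.5, and a catalog of MET VUS protein changes with predictor
#' profiles. The copula parameter is calibrated at generation time so the
#' *raw-scale* sample Pearson correlation between fusion reads and
#' zero-imputed DNA alt-coverage converges to the requested `rho`.
#'
#' @name cohort_synth
NULL

#' Simulation configuration
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed governing all randomness of one run.
#' @param met_variant_prevalence Fraction of patients with any MET variant.
#' @param fusion_detected_given_met Fraction of MET-variant patients with a
#'   retained exon13-exon15 fusion record.
#' @param log_read_mean,log_read_sd Log-normal parameters of the fusion
#'   read counts, truncated to `read_range`.
#' @param read_range Inclusive range of retained fusion read counts.
#' @param rho Target raw-scale Pearson correlation between fusion reads and
#'   zero-imputed DNA alt-coverage over the detected patients (|rho| < 1).
#' @param dna_dropout_given_rna_pos Probability that a fusion-detected
#'   patient's splice-window DNA variant is absent from the DNA data
#'   (applied uniformly over detected patients; on top of this, variants
#'   falling under the alt-read calling floor are zeroed by the filters,
#'   which is what makes low-read patients' DNA rescue rate lower).
#' @param log_cov_mean,log_cov_sd Log-normal parameters of DNA alt-coverage.
#' @param af_mixture List with `w_germline` (weight of the germline-like
#'   component), `somatic_shape` and `germline_shape` (Beta shape pairs).
#' @param vus_profile_frequencies Named weights over the VUS catalog used
#'   for MET carriers without a retained fusion record.
#' @param other_gene_rates Named per-gene carriage probabilities used for
#'   co-occurring variants across the whole cohort.
#' @param filter_cfg [filter_config()] defining the calling floor used both
#'   in generation and in calibration.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 1560, seed = 1,
                       met_variant_prevalence = 123 / 1560,
                       fusion_detected_given_met = 72 / 123,
                       log_read_mean = 4.8, log_read_sd = 0.8,
                       read_range = c(21, 67000),
                       rho = 0.45,
                       dna_dropout_given_rna_pos = 0.539,
                       log_cov_mean = 3.0, log_cov_sd = 0.7,
                       af_mixture = list(w_germline = 0.15,
                                         somatic_shape = c(3, 12),
                                         germline_shape = c(25, 25)),
                       vus_profile_frequencies = c(T992I = 11, H1094Y = 6,
                                                   R988C = 3, P1009S = 2,
                                                   V1092I = 2, L983F = 1),
                       other_gene_rates = c(KRAS = 0.20, EGFR = 0.18,
                                            ALK = 0.09, ERBB2 = 0.08,
                                            BRAF = 0.03, ROS1 = 0.02,
                                            RET = 0.02, PIK3CA = 0.04,
                                            ESR1 = 0.01, ERBB4 = 0.01),
                       filter_cfg = filter_config()) {
  if (!.is_fraction(met_variant_prevalence) ||
      !.is_fraction(fusion_detected_given_met) ||
      !.is_fraction(dna_dropout_given_rna_pos)) {
    .fail("fractions must be in [0, 1]")
  }
  if (abs(rho) >= 1) .fail("|rho| must be < 1")
  if (log_read_sd <= 0 || log_cov_sd <= 0) .fail("log sds must be > 0")
  if (dna_dropout_given_rna_pos >= 1 && rho != 0) {
    .fail("rho != 0 is infeasible with 100% DNA dropout")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Shared core of calibration and generation: given standard-normal draws and
# uniforms, produce (reads, effective zero-imputed alt coverage) under
# copula parameter rho_c. The effective coverage applies dropout and the
# alt-read calling floor, exactly as the downstream filters would.
.sim_pairs <- function(cfg, rho_c, z1, eps, u_drop, af) {
  lo <- stats::pnorm((log(cfg$read_range[1]) - cfg$log_read_mean) / cfg$log_read_sd)
  hi <- stats::pnorm((log(cfg$read_range[2]) - cfg$log_read_mean) / cfg$log_read_sd)
  # truncate the read distribution by mapping z1 through its own cdf
  zt <- stats::qnorm(lo + (hi - lo) * stats::pnorm(z1))
  reads <- pmin(pmax(round(exp(cfg$log_read_mean + cfg$log_read_sd * zt)),
                     cfg$read_range[1]), cfg$read_range[2])
  z2 <- rho_c * zt + sqrt(1 - rho_c^2) * eps
  alt <- round(exp(cfg$log_cov_mean + cfg$log_cov_sd * z2))
  depth <- pmax(round(alt / af), alt)
  pass <- alt >= cfg$filter_cfg$min_alt_reads &
    depth >= cfg$filter_cfg$min_site_depth &
    af >= cfg$filter_cfg$min_af_snv
  eff <- ifelse(u_drop < cfg$dna_dropout_given_rna_pos | !pass, 0, alt)
  list(reads = reads, alt = alt, depth = depth, eff = eff, pass = pass)
}

.draw_af <- function(n, mix) {
  g <- runif(n) < mix$w_germline
  af <- numeric(n)
  af[g] <- rbeta(sum(g), mix$germline_shape[1], mix$germline_shape[2])
  af[!g] <- rbeta(sum(!g), mix$somatic_shape[1], mix$somatic_shape[2])
  pmin(pmax(af, 0.01), 0.99)
}

#' Calibrate the copula parameter for a target raw-scale correlation
#'
#' Monotone root-finding on common random numbers: the same large set of
#' normal/uniform draws (internal fixed seed; the caller's RNG state is
#' preserved) is pushed through the read/coverage transform for candidate
#' copula parameters until the raw-scale Pearson correlation of
#' (reads, zero-imputed coverage) matches `cfg$rho`. Because the sample
#' Pearson coefficient of skewed, zero-inflated data is attenuated at
#' finite n, the calibration targets the *expected sample correlation at a
#' reference cohort size* (`n_block`, default 10,000 detected pairs),
#' estimated by averaging block-wise correlations over the calibration
#' draws; this is the size regime the generator is meant to serve. Errors
#' when the target is unreachable under the configured dropout and calling
#' floor.
#'
#' @param cfg A [sim_config()].
#' @param n_cal Number of calibration draws.
#' @param n_block Reference sample size whose expected sample correlation
#'   is matched to `cfg$rho`.
#' @return The calibrated copula correlation (scalar in (-1, 1)).
#' @export
calibrate_copula_rho <- function(cfg, n_cal = 800000, n_block = 10000) {
  key <- rlang::hash(list(cfg$rho, cfg$log_read_mean, cfg$log_read_sd,
                          cfg$read_range, cfg$log_cov_mean, cfg$log_cov_sd,
                          cfg$dna_dropout_given_rna_pos, cfg$af_mixture,
                          unclass(cfg$filter_cfg), n_cal, n_block))
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(761003L)
  z1 <- rnorm(n_cal); eps <- rnorm(n_cal); u_drop <- runif(n_cal)
  af <- .draw_af(n_cal, cfg$af_mixture)
  blocks <- split(seq_len(n_cal), (seq_len(n_cal) - 1) %/% n_block)
  rfun <- function(rc) {
    p <- .sim_pairs(cfg, rc, z1, eps, u_drop, af)
    if (stats::var(p$eff) == 0) return(NA_real_)
    mean(vapply(blocks, function(ix) {
      if (stats::var(p$eff[ix]) == 0 || stats::var(p$reads[ix]) == 0) {
        return(NA_real_)
      }
      stats::cor(p$reads[ix], p$eff[ix])
    }, numeric(1)), na.rm = TRUE)
  }
  lo <- -0.999; hi <- 0.999
  r_lo <- rfun(lo); r_hi <- rfun(hi)
  if (is.na(r_lo) || is.na(r_hi)) {
    .fail("DNA coverage degenerate: rho target infeasible (all zero)")
  }
  if (cfg$rho < r_lo - 1e-6 || cfg$rho > r_hi + 1e-6) {
    .fail(sprintf(
      "target rho %.3f outside achievable range [%.3f, %.3f] for this config",
      cfg$rho, r_lo, r_hi))
  }
  root <- stats::uniroot(function(rc) rfun(rc) - cfg$rho, c(lo, hi),
                         tol = 1e-3)$root
  .calib_cache[[key]] <- root
  root
}

.calib_cache <- new.env(parent = emptyenv())

.vus_catalog <- function() {
  data.frame(
    variant_id = c("T992I", "H1094Y", "R988C", "P1009S", "V1092I", "L983F",
                   "H1086R"),
    gene = "MET",
    protein_change = c("T992I", "H1094Y", "R988C", "P1009S", "V1092I",
                       "L983F", "H1086R"),
    chromosome = "7",
    pos = c(116411990L, 116417464L, 116411978L, 116412041L, 116417440L,
            116411963L, 116417416L),
    ref = c("C", "C", "C", "C", "G", "C", "A"),
    alt = c("T", "T", "T", "T", "A", "T", "G"),
    sift = c("deleterious", "deleterious", "tolerated", "deleterious",
             "tolerated", "deleterious", "deleterious"),
    polyphen2 = c("probably_damaging", "probably_damaging",
                  "possibly_damaging", "possibly_damaging", "benign",
                  "benign", "probably_damaging"),
    mutation_taster = c("disease_causing", "disease_causing",
                        "disease_causing", "disease_causing", "neutral",
                        "disease_causing", "disease_causing"),
    cadd_phred = c(33.0, 28.4, 26.1, 27.3, 12.6, 25.0, 24.0),
    cgi = c("predicted_driver", "predicted_driver", "predicted_driver",
            "predicted_driver", "predicted_passenger", "predicted_passenger",
            "predicted_driver"),
    clinical_significance = "VUS",
    stringsAsFactors = FALSE)
}

.other_gene_loci <- function() {
  data.frame(
    gene = c("KRAS", "EGFR", "ALK", "ERBB2", "BRAF", "ROS1", "RET",
             "PIK3CA", "ESR1", "ERBB4", "IDH2", "MTOR"),
    chromosome = c("12", "7", "2", "17", "7", "6", "10", "3", "6", "2",
                   "15", "1"),
    pos = c(25398284L, 55259515L, 29443695L, 37880220L, 140453136L,
            117658500L, 43617416L, 178936091L, 152419923L, 212578380L,
            90631934L, 11288758L),
    ref = c("G", "T", "G", "A", "A", "C", "G", "G", "C", "G", "C", "T"),
    alt = c("T", "G", "A", "G", "T", "T", "A", "A", "T", "A", "T", "C"),
    stringsAsFactors = FALSE)
}

.splice_variant_templates <- function(windows) {
  d1 <- windows$donor[1]
  a2 <- windows$acceptor[2]
  data.frame(
    kind = c("donor_snv", "donor_del", "acceptor_snv"),
    chromosome = windows$chromosome,
    pos = c(d1 + 2L, d1 - 7L, a2 - 2L),
    ref = c("G", paste(rep("C", 15), collapse = ""), "A"),
    alt = c("T", "C", "G"),
    stringsAsFactors = FALSE)
}

.clinical_levels <- list(
  sex = c(women = 0.537, men = 0.463),
  country = c(Chile = 0.713, Brazil = 0.204, Peru = 0.083),
  stage = c(IV = 0.63, III = 0.20, II = 0.10, I = 0.07),
  smoking = c(never = 0.306, former = 0.525, current = 0.169))

#' Simulate a synthetic cohort
#'
#' See [sim_config()] for the generative model. All randomness is governed
#' by `cfg$seed`; the same configuration reproduces the same cohort
#' bit-for-bit.
#'
#' @param cfg A [sim_config()].
#' @param windows Splice windows used for the DNA splice variants; default:
#'   exon 14 of the packaged MET model.
#' @return A `metex_cohort` object: list with `patients`, `variants`,
#'   `fusions`, `qc`, `annotations`, `manifest`.
#' @export
simulate_cohort <- function(cfg = sim_config(), windows = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(windows)) {
    gm <- met_gene_model()
    windows <- build_splice_windows(gm$model, 14, gm$windows)
  }
  rho_c <- calibrate_copula_rho(cfg)
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("S%05d", seq_len(n))
  n_met <- round(cfg$met_variant_prevalence * n)
  met_ids <- sort(sample(ids, n_met))
  n_det <- round(cfg$fusion_detected_given_met * n_met)
  det_ids <- sort(sample(met_ids, n_det))
  nondet_ids <- setdiff(met_ids, det_ids)

  ## fusion reads + correlated DNA coverage for the detected patients
  z1 <- rnorm(n_det); eps <- rnorm(n_det); u_drop <- runif(n_det)
  af <- .draw_af(n_det, cfg$af_mixture)
  pr <- .sim_pairs(cfg, rho_c, z1, eps, u_drop, af)
  tmpl <- .splice_variant_templates(windows)
  kind <- sample(c("donor_snv", "donor_del", "acceptor_snv"), n_det,
                 replace = TRUE, prob = c(0.7, 0.15, 0.15))
  has_record <- u_drop >= cfg$dna_dropout_given_rna_pos

  variants <- list()
  ti <- match(kind, tmpl$kind)
  is_indel <- nchar(tmpl$ref[ti]) != nchar(tmpl$alt[ti])
  qual <- round(ifelse(is_indel, 25 + 30 * runif(n_det),
                       10 + 40 * runif(n_det)), 1)
  keep <- has_record
  if (any(keep)) {
    variants[[length(variants) + 1L]] <- data.frame(
      patient_id = det_ids[keep], chromosome = tmpl$chromosome[ti][keep],
      pos = tmpl$pos[ti][keep], ref = tmpl$ref[ti][keep],
      alt = tmpl$alt[ti][keep],
      allele_frequency = round(pr$alt[keep] / pr$depth[keep], 4),
      site_depth = pr$depth[keep], alt_reads = pr$alt[keep],
      quality_phred = qual[keep],
      gene = "MET", protein_change = NA_character_,
      stringsAsFactors = FALSE)
  }

  ## non-detected MET carriers get a VUS from the catalog
  catalog <- .vus_catalog()
  w <- cfg$vus_profile_frequencies
  if (length(nondet_ids)) {
    vus_pick <- sample(names(w), length(nondet_ids), replace = TRUE,
                       prob = w / sum(w))
    ci <- match(vus_pick, catalog$variant_id)
    alt <- pmax(10L, round(exp(3.5 + 0.8 * rnorm(length(nondet_ids)))))
    afv <- .draw_af(length(nondet_ids), cfg$af_mixture)
    depth <- pmax(round(alt / afv), alt, 50L)
    variants[[length(variants) + 1L]] <- data.frame(
      patient_id = nondet_ids, chromosome = catalog$chromosome[ci],
      pos = catalog$pos[ci], ref = catalog$ref[ci], alt = catalog$alt[ci],
      allele_frequency = round(alt / depth, 4),
      site_depth = depth, alt_reads = alt,
      quality_phred = round(15 + 40 * runif(length(nondet_ids)), 1),
      gene = "MET", protein_change = catalog$protein_change[ci],
      stringsAsFactors = FALSE)
  }

  ## co-occurring variants in other genes, cohort-wide
  loci <- .other_gene_loci()
  for (g in names(cfg$other_gene_rates)) {
    carriers <- ids[runif(n) < cfg$other_gene_rates[[g]]]
    if (!length(carriers)) next
    lg <- loci[loci$gene == g, ]
    alt <- pmax(10L, round(exp(3.5 + 0.8 * rnorm(length(carriers)))))
    afv <- .draw_af(length(carriers), cfg$af_mixture)
    depth <- pmax(round(alt / afv), alt, 50L)
    variants[[length(variants) + 1L]] <- data.frame(
      patient_id = carriers, chromosome = lg$chromosome, pos = lg$pos,
      ref = lg$ref, alt = lg$alt,
      allele_frequency = round(alt / depth, 4),
      site_depth = depth, alt_reads = alt,
      quality_phred = round(15 + 40 * runif(length(carriers)), 1),
      gene = g, protein_change = NA_character_,
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  ## fusion table: retained records for detected patients plus a few
  ## sub-floor records that the RNA filter will drop
  fusions <- data.frame(
    patient_id = det_ids, fusion_id = "MET-MET.M13M15",
    five_prime_exon = 13L, three_prime_exon = 15L,
    read_count = pr$reads, stringsAsFactors = FALSE)
  sub <- nondet_ids[runif(length(nondet_ids)) < 0.1]
  if (length(sub)) {
    fusions <- rbind(fusions, data.frame(
      patient_id = sub, fusion_id = "MET-MET.M13M15",
      five_prime_exon = 13L, three_prime_exon = 15L,
      read_count = sample(1:20, length(sub), replace = TRUE),
      stringsAsFactors = FALSE))
  }

  qc <- data.frame(
    patient_id = ids,
    median_reads_per_amplicon = round(260 + 400 * runif(n)),
    pct_aligned_reads = round(75 + 24 * runif(n), 1),
    rna_mapped_reads = round(50000 + 900000 * runif(n)),
    expression_controls_detected = sample(3:5, n, replace = TRUE),
    stringsAsFactors = FALSE)

  draw_level <- function(probs, k) {
    sample(names(probs), k, replace = TRUE, prob = probs)
  }
  patients <- data.frame(
    patient_id = ids, met_carrier = ids %in% met_ids,
    sex = draw_level(.clinical_levels$sex, n),
    country = draw_level(.clinical_levels$country, n),
    stage = draw_level(.clinical_levels$stage, n),
    smoking = draw_level(.clinical_levels$smoking, n),
    stringsAsFactors = FALSE)

  manifest <- list(
    generator = "simulate_cohort",
    seed = cfg$seed,
    config_hash = rlang::hash(unclass(cfg)),
    rho_target = cfg$rho, rho_copula = rho_c,
    n_patients = n, n_met = n_met, n_fusion_detected = n_det,
    lowread_denominator = sum(pr$reads < 120))
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

#' @export
print.metex_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<metex_cohort> %d patients, %d MET carriers, %d fusion-detected (%s)\n",
    m$n_patients, m$n_met, m$n_fusion_detected, m$generator))
  invisible(x)
}

#' Patient-gene table of a cohort
#'
#' One row per (patient, gene): union of DNA variant genes and MET carriage
#' implied by any fusion record.
#'
#' @param cohort A `metex_cohort`.
#' @return `data.frame` with `patient_id`, `gene`.
#' @export
cohort_patient_genes <- function(cohort) {
  pg <- rbind(
    cohort$variants[, c("patient_id", "gene")],
    data.frame(patient_id = cohort$fusions$patient_id, gene = "MET",
               stringsAsFactors = FALSE))
  unique(pg[order(pg$patient_id, pg$gene), , drop = FALSE])
}

#' Write a cohort to disk
#'
#' VCF 4.2 (per-patient files or one combined multi-sample file), fusion /
#' QC / annotation / clinical TSVs and a JSON manifest. Every file header
#' embeds the seed and configuration hash.
#'
#' @param cohort A `metex_cohort`.
#' @param dir Output directory.
#' @param combined_vcf Write a single multi-sample VCF instead of
#'   per-patient files.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir, combined_vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  note <- sprintf("seed=%s config=%s", cohort$manifest$seed,
                  cohort$manifest$config_hash)
  write_variant_vcf(cohort$variants, file.path(dir, "vcf"),
                    combined = combined_vcf, header_note = note)
  write_metexdx_tsv(cohort$fusions, file.path(dir, "fusions.tsv"), note)
  write_metexdx_tsv(cohort$qc, file.path(dir, "qc_metrics.tsv"), note)
  write_metexdx_tsv(cohort$annotations, file.path(dir, "annotations.tsv"), note)
  write_metexdx_tsv(cohort$patients, file.path(dir, "clinical.tsv"), note)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a written cohort back
#'
#' @param dir Directory produced by [write_cohort()].
#' @return A `metex_cohort`.
#' @export
read_cohort <- function(dir) {
  vdir <- file.path(dir, "vcf")
  variants <- if (file.exists(file.path(vdir, "cohort.vcf"))) {
    read_vcf_variants(file.path(vdir, "cohort.vcf"))
  } else {
    read_vcf_dir(vdir)
  }
  structure(list(
    patients = read_metexdx_tsv(file.path(dir, "clinical.tsv")),
    variants = variants,
    fusions = read_fusion_table(file.path(dir, "fusions.tsv")),
    qc = read_qc_table(file.path(dir, "qc_metrics.tsv")),
    annotations = read_annotation_table(file.path(dir, "annotations.tsv")),
    manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                   simplifyVector = TRUE)),
    class = "metex_cohort")
}
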