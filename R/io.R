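#' File formats
#'
#' DNA variants enter as VCF 4.2 (read through vcfR), RNA fusion evidence,
#' QC metrics and predictor annotations as tab-separated tables with `#`
#' comment headers. Writers embed the generator seed and configuration hash
#' in a header comment so every artefact is traceable to its run.
#'
#' @name io
NULL

.default_field_map <- list(af = "AF", dp = "DP", ao = "AO", ad = "AD")
.default_info_map <- list(gene = "GENE", protein_change = "PCHANGE")

#' Read DNA small variants from a VCF 4.2 file
#'
#' Returns one row per (sample, record, alt allele): multi-allelic records
#' are split before filtering. Allele frequency, site depth and
#' alt-supporting reads come from the per-sample `AF`/`DP`/`AO` FORMAT
#' fields (configurable; `AD` is used for alt reads when `AO` is absent).
#' Gene symbol and protein change come from the INFO keys in `info_map`.
#' Samples without supporting reads for a record are skipped.
#'
#' @param path VCF file path.
#' @param field_map Named list mapping `af`, `dp`, `ao` (and fallback `ad`)
#'   to FORMAT field IDs.
#' @param info_map Named list mapping `gene` and `protein_change` to INFO
#'   keys.
#' @return `data.frame` with columns `patient_id`, `chromosome`, `pos`,
#'   `ref`, `alt`, `allele_frequency`, `site_depth`, `alt_reads`,
#'   `quality_phred`, `gene`, `protein_change`.
#' @export
read_vcf_variants <- function(path, field_map = .default_field_map,
                              info_map = .default_info_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- v@fix
  if (is.null(dim(fixm))) fixm <- matrix(fixm, nrow = 1,
                                         dimnames = list(NULL, names(fixm)))
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) return(.empty_variant_df())
  info_get <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (length(x)) x[x %in% c(".", "")] <- NA_character_
    x
  }
  gene <- info_get(info_map$gene)
  pchange <- info_get(info_map$protein_change)
  samples <- colnames(v@gt)[-1]
  gt_get <- function(el) {
    m <- tryCatch(suppressWarnings(vcfR::extract.gt(v, element = el)),
                  error = function(e) NULL)
    if (!is.null(m) && all(is.na(m))) NULL else m
  }
  af <- gt_get(field_map$af)
  dp <- gt_get(field_map$dp)
  ao <- gt_get(field_map$ao)
  ad <- if (is.null(ao)) gt_get(field_map$ad) else NULL

  out <- list()
  for (s in samples) {
    for (i in seq_len(nrow(fix))) {
      afi <- af[i, s]
      if (is.na(afi)) next
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      afs <- as.numeric(strsplit(afi, ",", fixed = TRUE)[[1]])
      aos <- if (!is.null(ao)) {
        as.numeric(strsplit(ao[i, s], ",", fixed = TRUE)[[1]])
      } else {
        # AD lists ref followed by each alt
        as.numeric(strsplit(ad[i, s], ",", fixed = TRUE)[[1]])[-1]
      }
      dpi <- as.numeric(dp[i, s])
      for (k in seq_along(alts)) {
        if (is.na(aos[k]) || aos[k] <= 0) next
        out[[length(out) + 1L]] <- data.frame(
          patient_id = s, chromosome = fix$CHROM[i],
          pos = as.integer(fix$POS[i]), ref = fix$REF[i], alt = alts[k],
          allele_frequency = afs[k], site_depth = dpi, alt_reads = aos[k],
          quality_phred = as.numeric(fix$QUAL[i]),
          gene = if (length(gene)) gene[i] else NA_character_,
          protein_change = if (length(pchange)) pchange[i] else NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(.empty_variant_df())
  do.call(rbind, out)
}

.empty_variant_df <- function() {
  data.frame(patient_id = character(0), chromosome = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             allele_frequency = numeric(0), site_depth = numeric(0),
             alt_reads = numeric(0), quality_phred = numeric(0),
             gene = character(0), protein_change = character(0),
             stringsAsFactors = FALSE)
}

#' Read all per-patient VCFs in a directory
#'
#' @param dir Directory containing `*.vcf` files.
#' @inheritParams read_vcf_variants
#' @return Row-bound [read_vcf_variants()] output.
#' @export
read_vcf_dir <- function(dir, field_map = .default_field_map,
                         info_map = .default_info_map) {
  files <- list.files(dir, pattern = "\\.vcf$", full.names = TRUE)
  do.call(rbind, c(list(.empty_variant_df()),
                   lapply(files, read_vcf_variants, field_map = field_map,
                          info_map = info_map)))
}

#' Write a variant table as VCF 4.2
#'
#' One single-sample VCF per patient (`<dir>/<patient_id>.vcf`) or one
#' combined multi-sample VCF. Per-sample fields are `GT:DP:AO:AF`; gene and
#' protein change go to INFO (`GENE`, `PCHANGE`).
#'
#' @param variants Variant `data.frame` (see [read_vcf_variants()]).
#' @param dir Output directory (created if needed).
#' @param combined Write one multi-sample VCF (`cohort.vcf`) instead of
#'   per-patient files.
#' @param header_note Extra `##` header line content (e.g. seed/config
#'   fingerprint).
#' @return Invisibly, the written file path(s).
#' @export
write_variant_vcf <- function(variants, dir, combined = FALSE,
                              header_note = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=metexdx %s",
                   as.character(utils::packageVersion("metexdx"))),
           if (!is.null(header_note)) paste0("##metexdx_run=", header_note),
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=PCHANGE,Number=1,Type=String,Description=\"Protein change\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Site depth\">",
           "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alt observation count\">",
           "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">")
  body_row <- function(v, sample_cols) {
    info <- sprintf("GENE=%s;PCHANGE=%s", v$gene,
                    ifelse(is.na(v$protein_change) | v$protein_change == "",
                           ".", v$protein_change))
    paste(c(v$chromosome, v$pos, ".", v$ref, v$alt,
            format(v$quality_phred, trim = TRUE), "PASS", info,
            "GT:DP:AO:AF", sample_cols), collapse = "\t")
  }
  fmt_sample <- function(v) sprintf("0/1:%d:%d:%s", as.integer(v$site_depth),
                                    as.integer(v$alt_reads),
                                    format(v$allele_frequency, trim = TRUE))
  if (combined) {
    samples <- sort(unique(variants$patient_id))
    lines <- hdr
    lines <- c(lines, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                              "FILTER", "INFO", "FORMAT", samples),
                            collapse = "\t"))
    ord <- order(variants$chromosome, variants$pos, variants$patient_id)
    for (i in ord) {
      v <- variants[i, ]
      cols <- rep("./.:.:.:.", length(samples))
      cols[match(v$patient_id, samples)] <- fmt_sample(v)
      lines <- c(lines, body_row(v, cols))
    }
    path <- file.path(dir, "cohort.vcf")
    writeLines(lines, path)
    return(invisible(path))
  }
  paths <- character(0)
  for (p in sort(unique(variants$patient_id))) {
    vs <- variants[variants$patient_id == p, , drop = FALSE]
    vs <- vs[order(vs$chromosome, vs$pos), , drop = FALSE]
    lines <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                            "FILTER", "INFO", "FORMAT", p), collapse = "\t"))
    for (i in seq_len(nrow(vs))) {
      lines <- c(lines, body_row(vs[i, ], fmt_sample(vs[i, ])))
    }
    path <- file.path(dir, paste0(p, ".vcf"))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read / write the package's tab-separated tables
#'
#' All tables are plain TSV with a header row; lines starting with `#` are
#' comments. `write_metexdx_tsv()` prepends a comment recording the package
#' version and an optional run note (seed + configuration hash).
#'
#' @param path File path.
#' @param x `data.frame` to write.
#' @param header_note Optional run note for the header comment.
#' @return `read_metexdx_tsv()`: a `data.frame`.
#' @export
read_metexdx_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname read_metexdx_tsv
#' @export
write_metexdx_tsv <- function(x, path, header_note = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# metexdx %s%s",
                     as.character(utils::packageVersion("metexdx")),
                     if (is.null(header_note)) "" else paste0(" | ", header_note)),
             con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an RNA fusion table
#'
#' Expected columns: `patient_id`, `fusion_id`, `five_prime_exon`,
#' `three_prime_exon`, `read_count`.
#'
#' @param path TSV path.
#' @return `data.frame`; negative read counts are rejected.
#' @export
read_fusion_table <- function(path) {
  f <- read_metexdx_tsv(path)
  req <- c("patient_id", "fusion_id", "five_prime_exon", "three_prime_exon",
           "read_count")
  if (!all(req %in% names(f))) .fail("fusion table missing required columns")
  if (any(f$read_count < 0)) .fail("negative fusion read count")
  f
}

#' Read a sample QC metrics table
#'
#' Expected columns: `patient_id`, `median_reads_per_amplicon`,
#' `pct_aligned_reads`, `rna_mapped_reads`, `expression_controls_detected`.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_qc_table <- function(path) {
  q <- read_metexdx_tsv(path)
  req <- c("patient_id", "median_reads_per_amplicon", "pct_aligned_reads",
           "rna_mapped_reads", "expression_controls_detected")
  if (!all(req %in% names(q))) .fail("QC table missing required columns")
  q
}

#' Read a predictor annotation table
#'
#' Precomputed predictor outputs, one row per variant: `variant_id`, `gene`,
#' `protein_change`, `sift` (deleterious/tolerated), `polyphen2`
#' (benign/possibly_damaging/probably_damaging), `mutation_taster`
#' (disease_causing/neutral), `cadd_phred` (numeric), `cgi`
#' (known_driver/predicted_driver/predicted_passenger),
#' `clinical_significance`.
#'
#' @param path TSV path.
#' @return `data.frame`.
#' @export
read_annotation_table <- function(path) {
  a <- read_metexdx_tsv(path)
  req <- c("variant_id", "gene", "protein_change", "sift", "polyphen2",
           "mutation_taster", "cadd_phred", "cgi", "clinical_significance")
  if (!all(req %in% names(a))) .fail("annotation table missing required columns")
  a
}

#' Read the actionability gene sets
#'
#' @param path YAML file with `any_solid` and `lung` gene lists; default is
#'   the packaged sets.
#' @return List with character vectors `any_solid` and `lung`.
#' @export
read_actionable_genes <- function(path = system.file(
    "extdata", "actionable_genes.yaml", package = "metexdx")) {
  y <- yaml::read_yaml(path)
  list(any_solid = as.character(y$any_solid), lung = as.character(y$lung))
}

#' Read a protein-domain table
#'
#' @param path TSV with columns `domain_name`, `start_residue`,
#'   `end_residue`; default is the packaged Met table.
#' @return `data.frame` sorted by `start_residue`; overlap is rejected.
#' @export
read_domain_table <- function(path = system.file(
    "extdata", "met_domains.tsv", package = "metexdx")) {
  d <- read_metexdx_tsv(path)
  req <- c("domain_name", "start_residue", "end_residue")
  if (!all(req %in% names(d))) .fail("domain table missing required columns")
  d <- d[order(d$start_residue), , drop = FALSE]
  if (any(d$start_residue > d$end_residue)) .fail("domain start > end")
  if (nrow(d) > 1 && any(d$start_residue[-1] <= d$end_residue[-nrow(d)])) {
    .fail("domains overlap")
  }
  d
}
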