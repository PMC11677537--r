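#' Gene models and splice-region windows
#'
#' A gene model holds the exon structure of one transcript (1-based, closed
#' genomic intervals, VCF `POS` semantics). From it, splice *acceptor* and
#' *donor* windows are derived around a chosen exon; DNA variants overlapping
#' those windows are the splice-region evidence used by the METex14
#' classifier. METex14-causing DNA variants cluster at the 3' splice
#' (acceptor) site of intron 13 and the 5' splice (donor) site of intron 14,
#' i.e. at the two boundaries of exon 14, and include SNVs as well as indels
#' of various lengths.
#'
#' @name gene_model
NULL

#' Construct a gene model
#'
#' @param gene_symbol Gene symbol, e.g. `"MET"`.
#' @param chromosome Chromosome name as used in the VCF, e.g. `"7"`.
#' @param strand `"+"` or `"-"`.
#' @param transcript_id Transcript accession the exon coordinates refer to.
#' @param exons `data.frame` with columns `exon_number`, `start`, `end`
#'   (1-based, closed). Exons must be non-overlapping with unique numbers.
#'
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_symbol, chromosome, strand, transcript_id, exons) {
  stopifnot(is.character(gene_symbol), is.character(chromosome))
  if (!strand %in% c("+", "-")) .fail("strand must be '+' or '-'")
  exons <- as.data.frame(exons)
  req <- c("exon_number", "start", "end")
  if (!all(req %in% names(exons))) {
    .fail("exons needs columns exon_number, start, end")
  }
  exons <- exons[order(exons$start), req, drop = FALSE]
  if (any(exons$start > exons$end)) .fail("exon start > end")
  if (anyDuplicated(exons$exon_number)) .fail("duplicate exon numbers")
  if (nrow(exons) > 1 &&
      any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    .fail("exons overlap")
  }
  structure(
    list(gene_symbol = gene_symbol, chromosome = chromosome, strand = strand,
         transcript_id = transcript_id, exons = exons),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s strand) chr%s, transcript %s, %d exons\n",
              x$gene_symbol, x$strand, x$chromosome, x$transcript_id,
              nrow(x$exons)))
  print(x$exons, row.names = FALSE)
  invisible(x)
}

#' Splice-window extents
#'
#' Window extents in base pairs around the exon boundaries. The acceptor
#' window covers `acceptor_intronic_bp` intronic bases upstream of the exon
#' start plus `acceptor_exonic_bp` exonic bases; the donor window covers
#' `donor_exonic_bp` exonic bases plus `donor_intronic_bp` intronic bases
#' downstream of the exon end (plus-strand orientation; minus-strand genes
#' are mirrored). Defaults (25/2/2/10) follow common METex14 reporting
#' practice: a generous intronic acceptor stretch to catch the branch
#' point/polypyrimidine-tract deletions, and the donor site with its
#' immediate intronic context. Every report records the extents used.
#'
#' @param acceptor_intronic_bp,acceptor_exonic_bp,donor_exonic_bp,donor_intronic_bp
#'   Non-negative integers; at least one must be positive.
#' @return A `window_config` list.
#' @export
window_config <- function(acceptor_intronic_bp = 25, acceptor_exonic_bp = 2,
                          donor_exonic_bp = 2, donor_intronic_bp = 10) {
  v <- c(acceptor_intronic_bp, acceptor_exonic_bp,
         donor_exonic_bp, donor_intronic_bp)
  if (!all(vapply(v, .is_count, logical(1)))) {
    .fail("window extents must be non-negative integers")
  }
  if (sum(v) == 0) .fail("at least one window extent must be > 0")
  structure(
    list(acceptor_intronic_bp = as.integer(acceptor_intronic_bp),
         acceptor_exonic_bp = as.integer(acceptor_exonic_bp),
         donor_exonic_bp = as.integer(donor_exonic_bp),
         donor_intronic_bp = as.integer(donor_intronic_bp)),
    class = "window_config"
  )
}

#' Build splice acceptor/donor windows for one exon
#'
#' On the plus strand the acceptor window is
#' `[exon_start - acceptor_intronic_bp, exon_start + acceptor_exonic_bp - 1]`
#' and the donor window is
#' `[exon_end - donor_exonic_bp + 1, exon_end + donor_intronic_bp]`
#' (1-based, closed). On the minus strand the biological acceptor lies at the
#' exon end and the donor at the exon start, so the two formulas are
#' mirrored. A window that would reach into an adjacent exon of the model is
#' rejected.
#'
#' @param model A [gene_model()].
#' @param exon_number Exon to build windows for.
#' @param cfg A [window_config()].
#' @return An object of class `splice_windows`: list with `exon_number`,
#'   `chromosome`, `acceptor = c(start, end)`, `donor = c(start, end)`.
#' @export
build_splice_windows <- function(model, exon_number, cfg = window_config()) {
  stopifnot(inherits(model, "gene_model"), inherits(cfg, "window_config"))
  i <- match(exon_number, model$exons$exon_number)
  if (is.na(i)) {
    .fail(sprintf("exon %s not in model", exon_number), "metexdx_lookup_error")
  }
  es <- model$exons$start[i]
  ee <- model$exons$end[i]
  if (model$strand == "+") {
    acceptor <- c(es - cfg$acceptor_intronic_bp, es + cfg$acceptor_exonic_bp - 1L)
    donor    <- c(ee - cfg$donor_exonic_bp + 1L, ee + cfg$donor_intronic_bp)
  } else {
    # mirror: biological acceptor at the exon end, donor at the exon start
    acceptor <- c(ee - cfg$acceptor_exonic_bp + 1L, ee + cfg$acceptor_intronic_bp)
    donor    <- c(es - cfg$donor_intronic_bp, es + cfg$donor_exonic_bp - 1L)
  }
  # degenerate zero-width side: represent as an empty interval (end < start)
  # is not allowed by the type; instead collapse to NULL-like NA pair
  if (acceptor[2] < acceptor[1]) acceptor <- c(NA_integer_, NA_integer_)
  if (donor[2] < donor[1]) donor <- c(NA_integer_, NA_integer_)

  other <- model$exons[-i, , drop = FALSE]
  for (w in list(acceptor, donor)) {
    if (anyNA(w)) next
    if (any(w[1] <= other$end & w[2] >= other$start)) {
      .fail("splice window extends into an adjacent exon")
    }
  }
  structure(
    list(exon_number = exon_number, chromosome = model$chromosome,
         strand = model$strand, acceptor = acceptor, donor = donor,
         config = cfg),
    class = "splice_windows"
  )
}

#' @export
print.splice_windows <- function(x, ...) {
  cat(sprintf(
    "<splice_windows> exon %d chr%s: acceptor [%s, %s], donor [%s, %s]\n",
    x$exon_number, x$chromosome, x$acceptor[1], x$acceptor[2],
    x$donor[1], x$donor[2]))
  invisible(x)
}

#' Genomic interval affected by a small variant
#'
#' The reference footprint `[pos, pos + nchar(ref) - 1]`: an SNV collapses to
#' its single base, a deletion spans the deleted reference bases, and an
#' insertion is anchored at its single reference base. This is the interval
#' intersected with splice windows.
#'
#' @param ref,alt Allele strings (non-empty).
#' @param pos 1-based position of the first reference base.
#' @return Integer vector `c(start, end)`.
#' @export
variant_affected_interval <- function(ref, alt, pos) {
  if (!nzchar(ref) || !nzchar(alt)) .fail("empty allele string")
  if (!.is_count(pos) || pos < 1) .fail("pos must be a positive integer")
  c(as.integer(pos), as.integer(pos + nchar(ref) - 1L))
}

#' Which splice window does a variant hit?
#'
#' Closed-interval overlap of the variant's affected interval against the
#' acceptor and donor windows. Any overlap counts: a deletion that clips a
#' window without touching the canonical GT/AG dinucleotide is still
#' in-region, since splice-disrupting deletions of varying extent are
#' positive METex14 DNA evidence.
#'
#' @param chromosome Chromosome of the variant (must match the windows).
#' @param ref,alt,pos Variant alleles and position as in
#'   [variant_affected_interval()].
#' @param windows A [build_splice_windows()] result.
#' @return One of `"none"`, `"acceptor"`, `"donor"`, `"both"`.
#' @export
variant_in_splice_region <- function(chromosome, ref, alt, pos, windows) {
  stopifnot(inherits(windows, "splice_windows"))
  if (!identical(as.character(chromosome), as.character(windows$chromosome))) {
    .fail("variant and windows are on different chromosomes")
  }
  iv <- variant_affected_interval(ref, alt, pos)
  q <- IRanges::IRanges(start = iv[1], end = iv[2])
  hit <- function(w) {
    !anyNA(w) && IRanges::overlapsAny(q, IRanges::IRanges(w[1], w[2]))
  }
  a <- hit(windows$acceptor)
  d <- hit(windows$donor)
  if (a && d) "both" else if (a) "acceptor" else if (d) "donor" else "none"
}

#' Annotate a variant table with splice-region membership
#'
#' Vectorised wrapper over [variant_in_splice_region()]; adds a
#' `splice_region` column. Variants on other chromosomes get `"none"`.
#'
#' @param variants Variant `data.frame` with columns `chromosome`, `pos`,
#'   `ref`, `alt` (as produced by [read_vcf_variants()] or the simulator).
#' @param windows A [build_splice_windows()] result.
#' @return The input with a `splice_region` factor column.
#' @export
annotate_splice_region <- function(variants, windows) {
  stopifnot(is.data.frame(variants))
  n <- nrow(variants)
  out <- rep("none", n)
  same <- as.character(variants$chromosome) == as.character(windows$chromosome)
  if (any(same)) {
    iv <- IRanges::IRanges(
      start = as.integer(variants$pos[same]),
      end = as.integer(variants$pos[same] + nchar(variants$ref[same]) - 1L))
    hit <- function(w) {
      if (anyNA(w)) rep(FALSE, length(iv))
      else IRanges::overlapsAny(iv, IRanges::IRanges(w[1], w[2]))
    }
    a <- hit(windows$acceptor)
    d <- hit(windows$donor)
    out[same] <- ifelse(a & d, "both",
                        ifelse(a, "acceptor", ifelse(d, "donor", "none")))
  }
  variants$splice_region <- factor(out, levels = c("none", "acceptor",
                                                   "donor", "both"))
  variants
}

#' Read a gene-model configuration file
#'
#' YAML schema: `gene_symbol`, `chromosome`, `strand`, `transcript_id`,
#' `exons` (list of `{exon_number, start, end}`), and optionally `windows`
#' (`acceptor_intronic_bp`, `acceptor_exonic_bp`, `donor_exonic_bp`,
#' `donor_intronic_bp`). The packaged MET model is at
#' `system.file("extdata", "met_gene_model.yaml", package = "metexdx")`.
#'
#' @param path Path to the YAML file.
#' @return List with elements `model` ([gene_model()]) and `windows`
#'   ([window_config()], defaults if the file has no `windows` block).
#' @export
read_gene_model <- function(path) {
  y <- yaml::read_yaml(path)
  exons <- do.call(rbind, lapply(y$exons, function(e) {
    data.frame(exon_number = e$exon_number, start = e$start, end = e$end)
  }))
  model <- gene_model(y$gene_symbol, as.character(y$chromosome), y$strand,
                      y$transcript_id, exons)
  wcfg <- if (is.null(y$windows)) window_config() else do.call(window_config, y$windows)
  list(model = model, windows = wcfg)
}

#' Packaged MET (GRCh37) gene model
#'
#' Convenience loader for the shipped MET exon 13/14/15 model and default
#' window extents. Coordinates are configuration, not code: verify or
#' override them against your own annotation release via [read_gene_model()].
#'
#' @return As [read_gene_model()].
#' @export
met_gene_model <- function() {
  read_gene_model(system.file("extdata", "met_gene_model.yaml",
                              package = "metexdx"))
}
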