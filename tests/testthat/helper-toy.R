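# Shared toy fixtures, built in code.

toy_model <- function() {
  gene_model(
    gene_symbol = "MET", chromosome = "7", strand = "+",
    transcript_id = "TOY",
    exons = data.frame(exon_number = c(13, 14, 15),
                       start = c(114000, 115000, 116000),
                       end = c(114150, 115140, 116230)))
}

toy_windows <- function(cfg = window_config(25, 2, 2, 10)) {
  build_splice_windows(toy_model(), 14, cfg)
}

variant_df <- function(patient_id = "P1", chromosome = "7", pos = 115000,
                       ref = "A", alt = "G", allele_frequency = 0.2,
                       site_depth = 200, alt_reads = 40, quality_phred = 35,
                       gene = "MET", protein_change = NA_character_) {
  data.frame(patient_id = patient_id, chromosome = chromosome, pos = pos,
             ref = ref, alt = alt, allele_frequency = allele_frequency,
             site_depth = site_depth, alt_reads = alt_reads,
             quality_phred = quality_phred, gene = gene,
             protein_change = protein_change, stringsAsFactors = FALSE)
}

fusion_df <- function(patient_id = "P1", read_count = 150,
                      five_prime_exon = 13, three_prime_exon = 15) {
  data.frame(patient_id = patient_id, fusion_id = "MET-MET.M13M15",
             five_prime_exon = five_prime_exon,
             three_prime_exon = three_prime_exon,
             read_count = read_count, stringsAsFactors = FALSE)
}

# One cached reference cohort + analysis for the test session.
ref_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) co <<- build_reference_cohort()
    co
  }
})

ref_analysis <- local({
  an <- NULL
  function() {
    if (is.null(an)) an <<- analyze_cohort(ref_cohort())
    an
  }
})
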