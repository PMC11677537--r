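test_that("sample QC gates are inclusive at their printed thresholds", {
  # all four exactly at threshold -> pass
  expect_true(sample_qc_pass(240, 60, 20000, 3)$pass)
  # one epsilon below each gate in turn -> that gate fails
  r <- sample_qc_pass(239, 99, 1e6, 5)
  expect_false(r$pass)
  expect_identical(r$failed, "median_reads_per_amplicon")
  r <- sample_qc_pass(1000, 59.9, 1e6, 5)
  expect_identical(r$failed, "pct_aligned_reads")
  r <- sample_qc_pass(1000, 60, 19999, 3)
  expect_identical(r$failed, "rna_mapped_reads")
  r <- sample_qc_pass(1000, 60, 20000, 2)
  expect_identical(r$failed, "expression_controls_detected")
  # just above thresholds passes too
  expect_true(sample_qc_pass(240.1, 60.1, 20001, 4)$pass)
})

test_that("a missing QC metric fails with a missing gate", {
  r <- sample_qc_pass(NA, 80, 30000, 4)
  expect_false(r$pass)
  expect_identical(r$failed, "median_reads_per_amplicon:missing")
})

test_that("apply_sample_qc annotates a metrics table", {
  qc <- data.frame(patient_id = c("A", "B"),
                   median_reads_per_amplicon = c(300, 100),
                   pct_aligned_reads = c(90, 90),
                   rna_mapped_reads = c(1e5, 1e5),
                   expression_controls_detected = c(5, 5))
  out <- apply_sample_qc(qc)
  expect_identical(out$qc_pass, c(TRUE, FALSE))
  expect_identical(out$qc_failed_gates, c("", "median_reads_per_amplicon"))
})

test_that("variant class is SNV only for 1bp/1bp alleles", {
  expect_identical(classify_variant_type("A", "G"), "SNV")
  expect_identical(classify_variant_type("GATTACA", "G"), "INDEL")
  expect_identical(classify_variant_type("A", "ATT"), "INDEL")
  expect_identical(classify_variant_type(c("A", "AT"), c("G", "A")),
                   c("SNV", "INDEL"))
  expect_error(classify_variant_type("", "A"), "empty")
})

test_that("DNA filters are inclusive at every minimum", {
  keep <- function(...) passes_dna_filters(...)$keep
  # SNV at every boundary simultaneously
  expect_true(keep("A", "G", 0.05, 50, 10, 6))
  # each rule an epsilon below its bound
  r <- passes_dna_filters("A", "G", 0.049, 60, 12, 7)
  expect_false(r$keep); expect_identical(r$failed, "allele_frequency")
  r <- passes_dna_filters("A", "G", 0.05, 49, 12, 7)
  expect_false(r$keep); expect_identical(r$failed, "site_depth")
  r <- passes_dna_filters("A", "G", 0.05, 60, 9, 7)
  expect_false(r$keep); expect_identical(r$failed, "alt_reads")
  r <- passes_dna_filters("A", "G", 0.05, 60, 12, 5.9)
  expect_false(r$keep); expect_identical(r$failed, "quality")
  # indel-specific minima: AF 7%, Phred 20
  expect_true(keep("AT", "A", 0.07, 60, 12, 20))
  r <- passes_dna_filters("AT", "A", 0.069, 60, 12, 25)
  expect_false(r$keep); expect_identical(r$failed, "allele_frequency")
  r <- passes_dna_filters("AT", "A", 0.07, 60, 12, 19)
  expect_false(r$keep); expect_identical(r$failed, "quality")
  # an SNV AF between 5% and 7% passes while an indel does not
  expect_true(keep("A", "G", 0.06, 60, 12, 7))
  expect_false(keep("AT", "A", 0.06, 60, 12, 25))
})

test_that("failed variants are audited, not deleted", {
  v <- rbind(variant_df(allele_frequency = 0.2),
             variant_df(allele_frequency = 0.01, alt_reads = 2))
  out <- apply_dna_filters(v)
  expect_equal(nrow(out), 2)
  expect_identical(out$keep, c(TRUE, FALSE))
  expect_identical(out$drop_reasons[2], "allele_frequency;alt_reads")
})

test_that("AF inconsistent with depths is flagged, not dropped", {
  v <- variant_df(allele_frequency = 0.5, site_depth = 200, alt_reads = 40)
  out <- apply_dna_filters(v)
  expect_true(out$af_inconsistent)
  expect_true(out$keep)
  ok <- apply_dna_filters(variant_df(allele_frequency = 0.2,
                                     site_depth = 200, alt_reads = 40))
  expect_false(ok$af_inconsistent)
})

test_that("filters reject invalid variant records", {
  expect_error(apply_dna_filters(variant_df(alt_reads = 300, site_depth = 200)),
               "alt_reads exceeds")
  expect_error(apply_dna_filters(variant_df(allele_frequency = 1.2)),
               "outside")
})

test_that("RNA fusion filter is strictly more-than-20", {
  expect_true(passes_rna_filter(21))
  expect_false(passes_rna_filter(20))
  expect_false(passes_rna_filter(0))
  expect_error(passes_rna_filter(-1), "negative")
  f <- apply_rna_filter(fusion_df(read_count = c(20, 21)))
  expect_identical(f$keep, c(FALSE, TRUE))
})

test_that("raising any threshold never converts a drop into a keep", {
  set.seed(7)
  base <- filter_config()
  for (i in 1:60) {
    v <- variant_df(
      ref = sample(c("A", "AT"), 1), alt = "G",
      allele_frequency = runif(1, 0, 0.2),
      site_depth = sample(10:200, 1), alt_reads = 0, quality_phred = runif(1, 0, 40))
    v$alt_reads <- min(sample(0:40, 1), v$site_depth)
    stricter <- filter_config(
      min_af_snv = base$min_af_snv + runif(1, 0, 0.05),
      min_af_indel = base$min_af_indel + runif(1, 0, 0.05),
      min_alt_reads = base$min_alt_reads + sample(0:5, 1),
      min_site_depth = base$min_site_depth + sample(0:50, 1),
      min_phred_snv = base$min_phred_snv + runif(1, 0, 10),
      min_phred_indel = base$min_phred_indel + runif(1, 0, 10))
    k0 <- apply_dna_filters(v, base)$keep
    k1 <- apply_dna_filters(v, stricter)$keep
    expect_true(k0 || !k1)
  }
})

test_that("filtering is idempotent and order-independent", {
  set.seed(8)
  v <- do.call(rbind, lapply(1:20, function(i) {
    variant_df(patient_id = paste0("P", i),
               allele_frequency = runif(1, 0, 0.5),
               site_depth = sample(10:300, 1), alt_reads = sample(5:50, 1),
               quality_phred = runif(1, 0, 50))
  }))
  v$alt_reads <- pmin(v$alt_reads, v$site_depth)
  once <- apply_dna_filters(v)
  twice <- apply_dna_filters(once[, names(v)])
  expect_identical(once$keep, twice$keep)
  perm <- sample(nrow(v))
  shuffled <- apply_dna_filters(v[perm, ])
  expect_identical(shuffled$keep, once$keep[perm])
})

test_that("hotspot allow-list drops off-list positions when supplied", {
  v <- rbind(variant_df(pos = 100), variant_df(pos = 200))
  hs <- data.frame(chromosome = "7", pos = 100)
  out <- apply_dna_filters(v, hotspot = hs)
  expect_identical(out$keep, c(TRUE, FALSE))
  expect_identical(out$drop_reasons[2], "hotspot")
  # absent list: all positions eligible
  expect_true(all(apply_dna_filters(v)$keep))
})
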