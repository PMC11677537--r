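test_that("the decision table assigns the five categories", {
  expect_identical(as.character(classify_metex14(150, 0)$category),
                   "RNA_POSITIVE")
  expect_identical(as.character(classify_metex14(46, 1)$category),
                   "DNA_RESCUED")
  expect_identical(as.character(classify_metex14(46, 0)$category),
                   "UNDETERMINED")
  expect_identical(as.character(classify_metex14(0, 1)$category),
                   "DNA_ONLY_POSITIVE")
  expect_identical(as.character(classify_metex14(0, 0)$category),
                   "NEGATIVE")
  # boundaries: 120 is positive (at-least), 20 is undetected (more-than)
  expect_identical(as.character(classify_metex14(120, 0)$category),
                   "RNA_POSITIVE")
  expect_identical(as.character(classify_metex14(119, 0)$category),
                   "UNDETERMINED")
  expect_identical(as.character(classify_metex14(21, 0)$category),
                   "UNDETERMINED")
  expect_identical(as.character(classify_metex14(20, 1)$category),
                   "DNA_ONLY_POSITIVE")
  expect_error(classify_metex14(-5, 0), "negative")
})

test_that("categories are mutually exclusive and exhaustive", {
  set.seed(31)
  for (i in 1:500) {
    reads <- sample(0:200, 1)
    ndna <- sample(0:3, 1)
    r <- classify_metex14(reads, ndna)
    expect_true(as.character(r$category) %in%
                  c("RNA_POSITIVE", "DNA_RESCUED", "UNDETERMINED",
                    "DNA_ONLY_POSITIVE", "NEGATIVE"))
    # invariants of the type
    if (r$category == "RNA_POSITIVE") expect_gte(reads, 120)
    if (r$category == "DNA_RESCUED") {
      expect_true(reads > 20 && reads < 120 && ndna >= 1)
    }
    # determinism: same inputs, same category
    expect_identical(r$category, classify_metex14(reads, ndna)$category)
  }
})

test_that("raising the positive threshold never promotes a patient", {
  set.seed(32)
  for (i in 1:100) {
    reads <- sample(0:300, 1)
    ndna <- sample(0:2, 1)
    c0 <- classify_metex14(reads, ndna, classifier_config(120, 20))$category
    c1 <- classify_metex14(reads, ndna,
                           classifier_config(120 + sample(1:200, 1), 20))$category
    if (c0 != "RNA_POSITIVE") expect_true(c1 != "RNA_POSITIVE")
  }
})

test_that("cohort classification wires filters, windows and the table", {
  w <- toy_windows()
  fus <- fusion_df(patient_id = c("A", "B", "C", "E"),
                   read_count = c(150, 46, 46, 20))
  vars <- rbind(
    variant_df(patient_id = "B", pos = w$donor[1]),        # rescues B
    variant_df(patient_id = "D", pos = w$acceptor[1]),     # DNA-only D
    variant_df(patient_id = "C", pos = 115050),            # interior: no help
    variant_df(patient_id = "E", pos = w$donor[1]),        # E: fusion dropped
    variant_df(patient_id = "A", pos = w$donor[1],
               allele_frequency = 0.01, alt_reads = 2))    # filtered out
  calls <- classify_cohort(LETTERS[1:6], fus, vars, w)
  got <- setNames(as.character(calls$category), calls$patient_id)
  expect_identical(got[["A"]], "RNA_POSITIVE")
  expect_identical(got[["B"]], "DNA_RESCUED")
  expect_identical(got[["C"]], "UNDETERMINED")
  expect_identical(got[["D"]], "DNA_ONLY_POSITIVE")
  expect_identical(got[["E"]], "DNA_ONLY_POSITIVE")  # 20-read record dropped
  expect_identical(got[["F"]], "NEGATIVE")
  expect_equal(calls$dna_alt_coverage[calls$patient_id == "B"], 40)
  expect_equal(calls$dna_alt_coverage[calls$patient_id == "A"], 0)
})

test_that("cohort classification agrees with the scalar decision table", {
  set.seed(33)
  w <- toy_windows()
  ids <- sprintf("Q%02d", 1:40)
  reads <- sample(c(0, 5, 20, 21, 46, 119, 120, 500), 40, replace = TRUE)
  ndna <- sample(0:2, 40, replace = TRUE)
  fus <- fusion_df(patient_id = ids, read_count = reads)
  fus <- fus[fus$read_count > 0, ]
  vars <- do.call(rbind, lapply(which(ndna > 0), function(i) {
    variant_df(patient_id = ids[i], pos = w$donor[1])
  }))
  if (is.null(vars)) vars <- variant_df()[0, ]
  calls <- classify_cohort(ids, fus, vars, w)
  for (i in seq_along(ids)) {
    reads_retained <- if (reads[i] > 20) reads[i] else 0
    expected <- classify_metex14(reads_retained, min(ndna[i], 1))$category
    expect_identical(calls$category[calls$patient_id == ids[i]], expected)
  }
})

test_that("pearson matches hand-computed and definitional values", {
  expect_equal(pearson_with_zero_imputation(1:3, c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_with_zero_imputation(1:3, c(6, 4, 2))$r, -1.0)
  # hand computation: x = (1,2,3), y = (1,3,2): cov = 1/3, sd terms 2/3
  expect_equal(pearson_with_zero_imputation(1:3, c(1, 3, 2))$r, 0.5)
})

test_that("pearson agrees with the definitional formula to 1e-12", {
  pearson_def <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    r <- sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
    tt <- r * sqrt((length(x) - 2) / (1 - r^2))
    list(r = r, p = 2 * stats::pt(-abs(tt), length(x) - 2))
  }
  set.seed(34)
  for (i in 1:30) {
    n <- sample(3:50, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson_with_zero_imputation(x, y)
    want <- pearson_def(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("undetected DNA is imputed as zero before correlating", {
  x <- c(10, 100, 1000, 5000)
  y <- c(5, NA, 50, NA)
  got <- pearson_with_zero_imputation(x, y)
  expect_equal(got$r, stats::cor(x, c(5, 0, 50, 0)))
})

test_that("degenerate correlation inputs raise the undefined error", {
  expect_error(pearson_with_zero_imputation(1:2, 1:2),
               class = "metexdx_undefined_correlation")
  expect_error(pearson_with_zero_imputation(c(1, 1, 1), 1:3),
               class = "metexdx_undefined_correlation")
  expect_error(pearson_with_zero_imputation(1:3, c(NA, NA, NA)),
               class = "metexdx_undefined_correlation")
})

test_that("concordance summary counts are conserved", {
  w <- toy_windows()
  fus <- fusion_df(patient_id = sprintf("P%02d", 1:10),
                   read_count = c(150, 200, 3000, 125, 46, 30, 80, 110, 25, 90))
  vars <- rbind(variant_df(patient_id = "P05", pos = w$donor[1]),
                variant_df(patient_id = "P01", pos = w$donor[1],
                           alt_reads = 60, site_depth = 300))
  calls <- classify_cohort(sprintf("P%02d", 1:12), fus, vars, w)
  st <- concordance_summary(calls)
  expect_equal(st$n_rna_positive + st$n_undetermined_or_rescued,
               st$n_rna_detected)
  expect_equal(st$n_rna_detected, 10)
  expect_equal(st$frac_lowread_dna_rescued, 1 / 6)
  expect_equal(st$frac_rna_pos_dna_negative, 3 / 4)
  # an explicit reporting denominator overrides the subgroup size
  st5 <- concordance_summary(calls, lowread_denominator = 5)
  expect_equal(st5$frac_lowread_dna_rescued, 1 / 5)
})

test_that("all RNA-positives with DNA evidence give zero DNA-negative fraction", {
  w <- toy_windows()
  fus <- fusion_df(patient_id = c("A", "B", "C"), read_count = c(150, 300, 1000))
  vars <- do.call(rbind, lapply(c("A", "B", "C"), function(p) {
    variant_df(patient_id = p, pos = w$donor[1],
               alt_reads = c(A = 20, B = 40, C = 60)[[p]])
  }))
  calls <- classify_cohort(c("A", "B", "C"), fus, vars, w)
  # low-read group empty: correlation over it is undefined
  expect_error(concordance_summary(calls),
               class = "metexdx_undefined_correlation")
  expect_equal(mean(calls$n_dna_splice_variants == 0), 0)
})
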