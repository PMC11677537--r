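test_that("gene model validates exon structure", {
  expect_s3_class(toy_model(), "gene_model")
  expect_error(gene_model("G", "1", "+", "T",
                          data.frame(exon_number = 1, start = 10, end = 5)),
               "start > end")
  expect_error(gene_model("G", "1", "+", "T",
                          data.frame(exon_number = c(1, 2),
                                     start = c(10, 15), end = c(20, 30))),
               "overlap")
  expect_error(gene_model("G", "1", "+", "T",
                          data.frame(exon_number = c(1, 1),
                                     start = c(10, 100), end = c(20, 120))),
               "duplicate")
  expect_error(gene_model("G", "1", "x", "T",
                          data.frame(exon_number = 1, start = 1, end = 2)),
               "strand")
})

test_that("splice windows follow the boundary arithmetic", {
  w <- toy_windows()
  # exon 14 = [115000, 115140], cfg (25, 2, 2, 10)
  expect_equal(w$acceptor, c(114975, 115001))
  expect_equal(w$donor, c(115139, 115150))

  # degenerate single-base windows
  w1 <- toy_windows(window_config(0, 1, 1, 0))
  expect_equal(w1$acceptor, c(115000, 115000))
  expect_equal(w1$donor, c(115140, 115140))
})

test_that("windows from the shipped MET config match hand computation", {
  gm <- met_gene_model()
  w <- build_splice_windows(gm$model, 14, gm$windows)
  # exon 14 = [116411903, 116412043]; extents (25, 2, 2, 10):
  # acceptor = [116411903 - 25, 116411903 + 2 - 1]
  # donor    = [116412043 - 2 + 1, 116412043 + 10]
  expect_equal(w$acceptor, c(116411878, 116411904))
  expect_equal(w$donor, c(116412042, 116412053))
  expect_identical(w$chromosome, "7")
})

test_that("window construction errors are raised", {
  expect_error(build_splice_windows(toy_model(), 99), class = "metexdx_lookup_error")
  # acceptor reaching into exon 13 ([114000, 114150]): intron 13 is 849 bp
  expect_error(toy_windows(window_config(900, 2, 2, 10)), "adjacent exon")
  expect_error(window_config(-1, 2, 2, 10), "non-negative")
  expect_error(window_config(0, 0, 0, 0), "at least one")
})

test_that("minus-strand windows mirror the plus-strand formulas", {
  m <- gene_model("G", "1", "-", "T",
                  data.frame(exon_number = 1, start = 5000, end = 5100))
  w <- build_splice_windows(m, 1, window_config(25, 2, 2, 10))
  # biological acceptor at the exon end (downstream intron on - strand)
  expect_equal(w$acceptor, c(5099, 5125))
  expect_equal(w$donor, c(4990, 5001))
})

test_that("variant affected intervals follow the reference footprint", {
  expect_equal(variant_affected_interval("G", "T", 100), c(100, 100))
  expect_equal(variant_affected_interval("GATTACA", "G", 200), c(200, 206))
  expect_equal(variant_affected_interval("A", "ATT", 300), c(300, 300))
  expect_error(variant_affected_interval("", "T", 1), "empty")
  expect_error(variant_affected_interval("A", "", 1), "empty")
})

test_that("splice-region membership handles boundaries and partial overlap", {
  w <- toy_windows()
  # SNV exactly at donor start
  expect_identical(variant_in_splice_region("7", "A", "T", w$donor[1], w), "donor")
  # deletion straddling the donor start
  del_start <- w$donor[1] - 3
  expect_identical(
    variant_in_splice_region("7", strrep("A", 6), "A", del_start, w), "donor")
  # SNV strictly inside exon 14, outside both windows
  expect_identical(variant_in_splice_region("7", "A", "T", 115050, w), "none")
  # deletion spanning the whole exon hits both windows
  expect_identical(
    variant_in_splice_region("7", strrep("A", 200), "A", 114990, w), "both")
  expect_error(variant_in_splice_region("8", "A", "T", 115000, w),
               "different chromosome")
})

test_that("overlap decisions equal per-base enumeration", {
  w <- toy_windows()
  in_window <- function(s, e, win) any(seq(s, e) >= win[1] & seq(s, e) <= win[2])
  positions <- seq(w$acceptor[1] - 100, w$donor[2] + 100)
  for (len in c(1:5, 10, 25, 50)) {
    ref <- strrep("A", len)
    alt <- if (len == 1) "T" else "A"
    got <- vapply(positions, function(s) {
      variant_in_splice_region("7", ref, alt, s, w)
    }, character(1))
    a <- vapply(positions, function(s) in_window(s, s + len - 1, w$acceptor),
                logical(1))
    d <- vapply(positions, function(s) in_window(s, s + len - 1, w$donor),
                logical(1))
    want <- ifelse(a & d, "both", ifelse(a, "acceptor",
                                         ifelse(d, "donor", "none")))
    expect_identical(got, want, label = sprintf("length %d intervals", len))
  }
})

test_that("widening a window never turns a hit into none", {
  base <- window_config(5, 1, 1, 5)
  set.seed(42)
  for (i in 1:50) {
    pos <- sample(114950:115200, 1)
    len <- sample(1:20, 1)
    ref <- strrep("A", len)
    alt <- if (len == 1) "T" else "A"
    r0 <- variant_in_splice_region("7", ref, alt, pos, toy_windows(base))
    wider <- window_config(base$acceptor_intronic_bp + sample(0:20, 1),
                           base$acceptor_exonic_bp + sample(0:3, 1),
                           base$donor_exonic_bp + sample(0:3, 1),
                           base$donor_intronic_bp + sample(0:20, 1))
    r1 <- variant_in_splice_region("7", ref, alt, pos, toy_windows(wider))
    if (r0 != "none") expect_true(r1 != "none")
  }
})

test_that("single-sided window extents give exactly that many bases", {
  for (field in 1:4) {
    ext <- rep(0, 4)
    ext[field] <- 7
    w <- toy_windows(do.call(window_config, as.list(ext)))
    widths <- c(
      if (!anyNA(w$acceptor)) diff(w$acceptor) + 1 else 0,
      if (!anyNA(w$donor)) diff(w$donor) + 1 else 0)
    expect_equal(sum(widths), 7)
  }
})

test_that("gene-model config round-trips through yaml", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "gene_symbol: MET", "chromosome: '7'", "strand: '+'",
    "transcript_id: TOY", "exons:",
    "  - {exon_number: 14, start: 100, end: 200}",
    "windows: {acceptor_intronic_bp: 3, acceptor_exonic_bp: 1,",
    "          donor_exonic_bp: 1, donor_intronic_bp: 3}"), path)
  gm <- read_gene_model(path)
  expect_equal(gm$model$exons$start, 100)
  w <- build_splice_windows(gm$model, 14, gm$windows)
  expect_equal(w$acceptor, c(97, 100))
  expect_equal(w$donor, c(200, 203))
})
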