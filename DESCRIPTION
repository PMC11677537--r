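Package: metexdx
Title: Dual-Evidence Diagnosis of MET Exon 14 Skipping from Targeted
    DNA and RNA Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies non-small-cell lung cancer patients for the
    actionable MET exon 14 skipping variant (METex14) by combining RNA
    exon13-exon15 fusion read counts with DNA small variants falling in
    configurable splice acceptor/donor windows. Implements the
    sample-level quality-control gates and allele-frequency/depth/quality
    variant filters of a targeted amplicon panel, a five-way diagnostic
    decision table with an explicit undetermined zone and DNA rescue,
    RNA/DNA concordance statistics (Pearson correlation with
    zero-imputation for undetected DNA), consensus driver triage of MET
    variants of uncertain significance from precomputed
    SIFT/PolyPhen-2/MutationTaster/CADD/CGI annotations, protein-domain
    mapping, a co-occurring actionable variant screen, cohort prevalence
    tables with two-cohort Fisher comparisons, and a deterministic
    synthetic cohort generator (Gaussian-copula-correlated fusion reads
    and DNA coverage) so the whole pipeline is exercisable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    rlang,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
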