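Package: mtstamp
Title: Ultra-Deep Mitochondrial DNA Heteroplasmy Calling from Barcoded
    Read Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting low-frequency mitochondrial DNA (mtDNA)
    heteroplasmies from ultra-deep targeted sequencing with molecular
    barcodes (STAMP-style capture). Read families sharing a barcode are
    collapsed into consensus reads by a Bayesian per-column merge of base
    calls and base alignment qualities; consensus reads are screened
    against nuclear mitochondrial segments (NUMTs) by edit distance;
    variants with allele fractions down to 0.5% are called through a
    six-filter quality scheme including an exact Poisson error-rate test
    and a duplicate-concordance Fisher test; calls are annotated by
    genomic region, coding effect under the vertebrate mitochondrial
    genetic code, and a CADD/disease-based pathogenicity rule; and cohort
    mutation incidence is analysed with t-tests, age-adjusted logistic and
    multinomial models, and Poisson age-trend regressions. A synthetic
    read-family and cohort simulator provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    nnet,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
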