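Package: mpravar
Title: Design and Allelic Activity Analysis of Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for massively parallel reporter assay (MPRA) studies of
    regulatory variants: constrained oligonucleotide library design with
    scrambled-core controls and restriction-site-free barcodes, exact-match
    barcode counting from FASTQ, tag-count normalisation and filtering,
    per-variant allelic activity regression with heteroskedasticity-consistent
    (sandwich) Wald tests and Benjamini-Hochberg FDR, integration with eQTL
    direction, allele-specific expression and allelic-proteomics evidence, and
    a generative simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    lmtest,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
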