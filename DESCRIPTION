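Package: dirscreen
Title: Allele-Specific Reporter Screens for Regulatory SNP Nomination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for massively parallel reporter assay (MPRA)
    screens of candidate regulatory SNPs read out through barcoded reporter
    sequencing. Covers reporter library design (SNP-centered insert extraction,
    barcode assignment, primer/index sample sheets), simulation of barcoded
    amplicon sequencing with planted allelic activities, paired-read merging and
    demultiplexing, barcode counting, counts-per-million normalization,
    blank-calibrated allele activity estimation with two-stage regulatory SNP
    nomination (replicate t-test plus activity thresholds), hierarchical
    clustering of activity profiles with uncentered Pearson correlation,
    chromatin-peak support annotation of nominated SNPs, allele-aware position
    weight matrix scanning, and delta-delta-Ct style qPCR quantifications
    (ChIP/FAIRE enrichment, allele-specific qPCR, wild-type fraction after
    genome editing, allele-specific read counts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    ape,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    jsonlite,
    optparse
Config/testthat/edition: 3
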