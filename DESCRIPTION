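Package: sinreg
Title: Integrative Analysis of SIN3 Isoform Binding and Gene Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream analysis toolkit for transcription-factor and
    chromatin-complex regulatory genomics, built around the Drosophila SIN3
    isoforms. Assigns ChIP-seq peaks to genes with a strand-aware
    TSS-to-past-TES window, integrates peak-bound genes with differential
    expression to call repressed and activated direct targets, computes
    TSS-anchored metagene matrices and average binding profiles from
    bedGraph signal tracks, quantifies RNA polymerase II promoter-proximal
    pausing as a promoter-to-gene-body enrichment ratio compared between
    gene groups with the Mann-Whitney U test, classifies regulation strength
    by log2 fold-change bins and control expression (FPKM) categories, and
    detects hard-regulation candidates (activated targets silent in control
    cells). A fully labelled synthetic-data generator (annotation, peaks,
    signal, differential-expression and FPKM tables with ground truth) makes
    every pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
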