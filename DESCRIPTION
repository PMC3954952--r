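Package: agemeth
Title: Differential DNA Methylation and Age Classification for Two-Group Array Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide CpG methylation array data
    contrasting two age groups. Provides beta/M-value handling, per-probe
    Welch t-tests with Benjamini-Hochberg control and directional dmCpG
    calls, a genomic region catalog (gene segments, TSS/TES windows, CpG
    islands and shores, GC-skew promoter classes, chromosomes) with
    observed/expected log2 enrichment and exact hypergeometric tests,
    per-gene methylation summaries cross-tabulated against expression-change
    labels, and a single-probe stepwise-constant (decision stump) age
    classifier screened by leave-one-out cross-validation. Includes a
    seeded synthetic-data generator that emulates a 24-versus-24 study
    design with planted hypermethylation bias on an annotated toy genome.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
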