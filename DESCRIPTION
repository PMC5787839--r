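Package: bsmeth
Title: Whole-Genome Bisulfite Methylome Analysis with Simulated Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for plant whole-genome bisulfite
    sequencing (WGBS) methylome analysis. Classifies cytosines into CG, CHG
    and CHH contexts from a reference genome, estimates per-site methylation
    levels with correction for bisulfite nonconversion calibrated on an
    unmethylated lambda spike-in, summarizes methylation in sliding windows,
    calls differentially methylated regions (DMRs) between two conditions by
    windowed Fisher exact tests with false discovery rate control, tests
    genes and transposable elements for differential methylation, computes
    metagene and transposable-element methylation profiles with expression,
    methylation and length quintile stratifications, and integrates
    differential methylation with gene expression. Includes a fully seeded
    synthetic-data generator that emits an annotated genome, two-condition
    bisulfite count reports with planted DMRs, expression tables and a
    machine-readable truth set, so the whole pipeline is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
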