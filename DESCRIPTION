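Package: hkatlas
Title: Housekeeping-Gene Expression Pattern Analysis for Two-Group RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for comparing gene expression patterns between
    a normal and a cancer sample group from bulk RNA-Seq expression matrices.
    Estimates the expressed/not-expressed background threshold by coordinating
    false positive and false negative rates between exonic and intergenic
    signal, classifies genes into five housekeeping (HK) types by expression
    breadth, partitions expressed genes into low/moderate/high levels with a
    one-dimensional weighted k-medians, classifies expression variation with a
    rank-based coefficient of variation, quantifies cancer-versus-normal
    regulation with MDAD (span and mid-level differences of log2 group
    extremes) and maxR/minR extreme-value ratios tested by paired Wilcoxon
    signed-rank statistics, clusters sample profiles by Spearman correlation,
    and summarises gene-structure bias per HK class. Ships a synthetic-data
    generator emulating the two-group design with planted ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Config/testthat/edition: 3
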