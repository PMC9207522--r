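Package: oostage
Title: Stage-Resolved Oocyte Transcriptome Analysis with Paralog-Aware
    Ortholog Collapse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a stage-resolved bulk RNA-seq
    analysis of zebrafish oocyte development: low-count filtering,
    median-of-ratios normalization, negative-binomial likelihood-ratio and
    pairwise Wald tests with Benjamini-Hochberg adjustment, a
    baseMean-dependent fold-change filter for calling differentially
    expressed genes, k-means clustering of stage-expression trends, a
    paralog-aware zebrafish-to-human ortholog collapse with a
    directionality test, and hypergeometric over-representation analysis.
    Includes a negative-binomial count simulator with planted stage-trend
    archetypes and a synthetic orthology generator so the whole pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    MASS,
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
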