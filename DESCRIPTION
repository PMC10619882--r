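Package: gliatlas
Title: Quality Control, Annotation and Quantification Tools for Glial
    Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the bespoke computational
    procedures used to build a Drosophila glial single-cell atlas:
    quality-control filtering and log-normalization of count matrices,
    marker-threshold gating of neuronal and hemocyte contamination,
    batch-contribution cluster filtering, annotation of clusters by
    simulating pseudo-single cells from bulk cell-type transcriptomes and
    ranking Pearson correlations, an over-clustering criterion based on
    differential-expression gene counts, hypergeometric gene-set
    enrichment with redundancy reduction and Ward grouping, and
    quantification statistics for in-situ hybridization positivity,
    layer-binned cell volumes and clone proportions. Ships a synthetic
    data generator with planted ground truth so the whole pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
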