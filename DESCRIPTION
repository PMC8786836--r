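Package: pharynet
Title: Multi-Omic Regulatory Network Inference and In-Silico Knockout for
    Developmental Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the bespoke computational steps of
    a multi-omic (scRNA + scATAC) developmental atlas study of pharyngeal
    endoderm: auditable quality-control ledgers that reproduce printed cell
    counts, batch-covariate design construction with residual-dispersion gene
    selection and Marchenko-Pastur principal-component retention, chromatin
    peak annotation and cluster-specificity (tau) scoring, chromVAR-style
    motif deviation z-scores, co-accessibility from low-overlapping cell
    aggregates, CellOracle-style base-GRN assembly and bagging-ridge
    cluster-GRN refinement with in-silico transcription-factor knockout
    propagation, and knockout-versus-atlas projection, compositional
    abundance testing and pseudotime staging. Ships a seeded synthetic-data
    generator emulating the statistical structure the pipeline assumes, so
    every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
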