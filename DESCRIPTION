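Package: mqtlmeta
Title: Meta-QTL Analysis for Abiotic-Stress Tolerance on Consensus Genetic Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) meta-analysis in crop
    genetics, developed around chickpea abiotic-stress (drought, heat, cold,
    salinity) tolerance. Curates multi-study QTL catalogs (confidence-interval
    and LOD imputation, multi-environment de-duplication), builds a consensus
    genetic map from several population-specific linkage maps with
    redundant-marker renaming, ordering-conflict resolution and RMSE-based
    candidate selection, projects QTL onto the consensus map by homothetic
    scaling between shared anchor markers, and clusters projected QTL per
    linkage group with a one-dimensional Gaussian mixture model in which each
    observation carries a known variance derived from its 95% confidence
    interval. The number of meta-QTL (MQTL) is chosen by a five-criterion vote
    (AIC, AIC3, AICc, BIC, AWE). MQTL are then anchored physically via flanking
    markers, validated against marker-trait associations, screened with a
    breeder's rule, and mined for candidate genes in defined windows. A
    deterministic synthetic-data generator with known ground truth supports
    parameter-recovery experiments for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    igraph,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
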