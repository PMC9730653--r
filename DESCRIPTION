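Package: cpwave
Title: Spatiotemporal Analysis of Choroid Plexus and Perilesional
    Inflammation After Intracerebral Hemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the spatiotemporal dynamics of brain
    inflammation after experimental intracerebral hemorrhage. Annotates
    spatial transcriptomics spots anatomically via gene-set scoring with
    expression-matched control genes and Leiden clustering constrained to
    a target cluster count; performs region-stratified temporal
    differential expression against an uninjected control with
    Benjamini-Hochberg correction and hypergeometric gene-set enrichment;
    quantifies immunofluorescence sections through moments-based
    similarity registration, cross-animal average-intensity maps,
    dextran leakage area estimation, and per-compartment mean
    intensities; and summarises time courses with percentile-bootstrap
    confidence intervals, loess curves and peak calling. A synthetic-data
    generator plants the study's spatial, temporal and genotype structure
    (early choroid-plexus wave, delayed perilesional wave, biphasic
    blood-brain-barrier leakage, knockout suppression) with ground-truth
    labels for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    tiff,
    yaml,
    jsonlite,
    withr,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    fgsea,
    optparse
Config/testthat/edition: 3
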