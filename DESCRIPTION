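Package: seepBEF
Title: Biodiversity-Ecosystem Functioning Analysis Along Methane-Seep
    Resource Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing biodiversity-ecosystem functioning (BEF)
    relationships in benthic macrofaunal communities sampled along a
    chemosynthetic methane-seep activity gradient. Computes ecosystem
    functioning proxies (community bioturbation potential BPc,
    abundance-weighted calcification degree, faunal density and standing
    stock), taxonomic and functional-trait diversity (richness, Shannon,
    Pielou), environmental covariates (interpolated point measurements,
    annual net primary productivity and its depth-attenuated export flux,
    and slope/ruggedness/position indices from a bathymetry grid),
    per-grouping principal component reduction, and habitat-stratified
    generalized additive models with by-factor smooths, automatic
    family/link, knot and backward stepwise term selection, and
    classification of the fitted relationship shape (null, monotone,
    unimodal, complex). Includes a fully synthetic community generator
    with known ground-truth per-habitat BEF forms for power and recovery
    studies, and an end-to-end pipeline with machine-readable outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    mgcv,
    vegan,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
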