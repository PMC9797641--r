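Package: changevec
Title: Change-Vector Analysis of Microbial Community Ordinations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the direction and magnitude of microbial community
    change across replicate host populations using multivariate change
    vectors. Centroid difference vectors are fitted within one shared
    principal-coordinates ordination (from Bray-Curtis dissimilarity or any
    precomputed distance matrix, or externally supplied ordination scores);
    pairwise angles between vectors quantify (non)parallelism and vector
    lengths quantify magnitude. Significance is assessed by one-sample
    location tests against the 90-degree null, Monte-Carlo simulation of
    random-direction angle nulls, and Rayleigh tests of directional
    concentration. Includes strict readers and writers for tab-separated
    feature-table, taxonomy, metadata, design and distance-matrix
    interchange formats, rarefaction and taxonomy-level collapsing, a
    configurable end-to-end pipeline, and simulators with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
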