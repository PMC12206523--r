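Package: scibench
Title: Benchmarking Toolkit for Single-Cell Data Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the outputs of single-cell batch-integration methods with a
    two-category metric suite (batch correction and biological conservation),
    aggregates metrics into rescaled composite and overall scores for method
    ranking, and ships reference implementations of three classical integration
    baselines (ComBat-style empirical Bayes adjustment, mutual-nearest-neighbour
    correction, and batch-balanced kNN graphs) together with a ground-truth
    synthetic-data generator, so the whole evaluation loop runs without any
    external data. Metrics include the local inverse Simpson's index (iLISI and
    cLISI), the kBET chi-squared neighbourhood test, batch and cell-type average
    silhouette widths, principal-component regression, kernel-density overlap on
    principal components, graph connectivity, NMI, ARI, centroid-distance
    preservation (scGraph), and cell-cycle conservation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    cluster,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
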