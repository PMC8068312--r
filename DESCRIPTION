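Package: phytonet
Title: Multipartite Network Analysis of Medicinal Plants, Chemicals and
    Protein Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses tripartite networks linking medicinal
    plants to their chemical constituents and those chemicals to predicted
    protein targets. Provides a preprocessing cascade (non-plant removal,
    record deduplication, activity-probability thresholding, pruning of
    isolated nodes) with per-stage density accounting, spectral
    co-clustering of the network with modularity-based selection of the
    number of clusters, hierarchical clustering of plants by Bray-Curtis
    distance on binary chemical profiles with complete linkage, a Target
    Potency Score (TPS) for ranking targets against plant clusters and
    retrieving plant-chemical-target subnetworks, a seeded synthetic-data
    generator with planted plant blocks for end-to-end validation, and a
    one-call pipeline with a reproducible output manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    ape,
    Matrix,
    jsonlite,
    yaml,
    mclust,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
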