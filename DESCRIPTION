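Package: hetgo
Title: Heterogeneous Network Embedding and Hierarchical GO Function Prediction for miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates miRNA co-expression, protein-protein interaction and
    disease phenotype similarity networks with their bipartite association
    layers into a single weighted heterogeneous graph; learns low-dimensional
    node representations with a from-scratch LINE implementation (first- and
    second-order proximity, negative sampling); trains a GO-DAG-consistent
    hierarchical multi-label classifier (shared dense layer, per-term sigmoid
    heads, maximum-merge layers) on protein annotations and transfers it to
    miRNAs; and scores predictions with protein-centric Fmax over a threshold
    sweep. Ships a seeded synthetic benchmark generator so the whole pipeline
    runs at desk scale with no external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    broom,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
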