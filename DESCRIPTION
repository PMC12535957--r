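Package: topoconnectome
Title: Topological and Graph-Theoretical Features from Multimodal Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Persistent homology and graph-theoretical featurization of
    multimodal brain connectivity networks (morphological gray matter,
    FA-weighted structural connectivity, resting-state functional
    correlation) over a common parcellation. Implements flag (clique)
    filtrations of weighted graphs with boundary-matrix reduction over
    GF(2), Betti-curve vectorization, supra-adjacency multilayer network
    assembly, five node-level centrality metrics with a declared
    multilayer convention, edge-wise covariate residualization, a
    synthetic multimodal cohort generator, and a repeated stratified
    cross-validation AUC-ROC benchmark across four classifier families.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    glmnet,
    ranger,
    e1071,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
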