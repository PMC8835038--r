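Package: drugsense
Title: Network-Based Clustering and Prediction of Cell-Line Drug Sensitivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters cancer cell lines and drugs by optimal mass transport on
    networks and predicts log(IC50) drug response per paired cluster. Cell lines
    are represented as invariant measures of an expression-weighted Markov chain
    on a protein-interaction network; drugs as normalized cheminformatic feature
    distributions on a graphical-LASSO feature network. Pairwise exact W1
    (earth mover's) distances feed hierarchical clustering with silhouette-based
    model selection; random-forest regression is fitted within each
    cell-cluster/drug-cluster pair and compared with a dual-layer similarity
    (CDCN) closed form. Includes seeded synthetic-data generators, permutation
    importance plus t-test gene selection, and hypergeometric gene-set
    enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    ranger,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    boot,
    cluster,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
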