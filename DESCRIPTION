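Package: graphletsig
Title: Graphlet Signature Clustering for Functional-Genomics Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies candidate members of known biological pathways inside
    RNAi screen hit lists by topological similarity in a protein-protein
    interaction network. Summarizes each protein's neighbourhood with its
    graphlet degree vector (73 automorphism-orbit counts over all 2-5-node
    graphlets, counted exactly by connected-subgraph enumeration), clusters
    screen hits by weighted log-scale signature similarity with an adaptive
    threshold search, scores clusters for screen-hit enrichment with a
    hypergeometric test and a random-cluster permutation null, expands
    clusters into connected pathway subnetworks, and surveys pathway gene-set
    diameters. Includes a synthetic-data generator with planted pathway
    modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    methods,
    stats,
    utils,
    withr,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'orbit-constants.R'
    'catalog.R'
    'network-io.R'
    'gdv.R'
    'similarity.R'
    'screen-stats.R'
    'clustering.R'
    'enrichment.R'
    'expansion.R'
    'synthetic.R'
    'pipeline.R'
    'graphletsig-package.R'
    'RcppExports.R'
RoxygenNote: 7.3.3
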