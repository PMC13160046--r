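Package: fateflow
Title: Optimal Transport Fate Mapping for Longitudinal Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs cell fate dynamics from timepoint-labeled
    single-cell expression data using entropic unbalanced optimal
    transport. Fits growth-calibrated transport maps between adjacent
    timepoints, derives fate flows, trajectory kernel mean embeddings and
    trajectory clusters, fate entropy and consistency scores, compartment
    egress probabilities and tissue arrival times, lineage-stable gene
    programs, and debiased Sinkhorn distributional distances. Ships a
    ground-truthed two-compartment birth-death simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    cluster,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    boot,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
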