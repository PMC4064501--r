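Package: adaptcall
Title: Adaptive Cluster-Number Genotype Calling for Two-Channel SNP Arrays
Version: 0.1.0
Authors@R: person("adaptcall", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Converts raw two-channel SNP microarray intensities into
    genotype calls by between-sample quantile normalization of each
    allele channel, exact one-dimensional k-means clustering of
    log-ratios with a variable number of clusters k in {1,2,3} per SNP,
    logistic-regression prediction of k from cluster-quality features
    (residual sums of squares, Mahalanobis distances to consensus
    cluster centers, and Hardy-Weinberg goodness-of-fit statistics),
    and silhouette-width call confidences.  Includes gender imputation
    from chromosome-Y signal with sex-restricted calling on the sex
    chromosomes, an accuracy-versus-drop-rate evaluation toolkit, and a
    synthetic intensity simulator so that every stage of the pipeline
    is testable without array data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    MASS,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
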