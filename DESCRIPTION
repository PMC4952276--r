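Package: confens
Title: Per-Sample Confidence-Weighted Ensembles of Disjoint Sparse Linear Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains an ensemble of sparse linear classifiers on mutually disjoint
    feature subsets and combines them at prediction time with per-test-sample
    confidence weights. For every feature selected by a classifier, a Gaussian-process
    regressor (predictors chosen by the maximal information coefficient) models how
    predictable that feature is from the rest of the data; at test time the
    regressor's posterior turns the observed value into a per-feature reliability
    score, which is aggregated into per-classifier weights for a weighted vote.
    Designed for omics phenotype prediction (gene expression, DNA methylation) where
    parts of the test data may be shifted relative to the training data. Includes
    probe-to-gene preprocessing, interpretability graphs (per-sample classifier and
    feature graphs, protein-interaction subnetworks, co-occurrence graphs with
    kernel-density percentile pruning), and a synthetic block-correlated data
    generator with a repeated-split AUC benchmark harness.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
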