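Package: pecnet
Title: Source-Space Power-Envelope Connectivity and Brain-Network Topology for Task EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for task-EEG functional brain networks: synthetic
    cohort generation with planted envelope couplings, broadband preprocessing
    (zero-phase band filtering, downsampling, common-average reference, epoching
    with baseline correction), weighted minimum-norm source estimation,
    orthogonalized power-envelope connectivity (PEC) with ROI aggregation,
    binary graph-topology metrics (clustering coefficient, characteristic path
    length, small-worldness, global and local efficiency) against a
    degree-preserving connected random-network null, edge-wise and behavioral
    group statistics with Bonferroni correction, and a leave-one-subject-out
    feature-selection classification framework (Corr/Fisher/ReliefF/LARS
    rankings crossed with logistic-regression, AdaBoost, decision-tree and
    random-forest classifiers).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    glmnet,
    rpart,
    randomForest,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
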