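Package: connectoclass
Title: Classifying Post-Surgical Naming Decline from Structural Connectome Change
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers binary picture-naming decline after anterior temporal lobe
    resection from the estimated pre- to post-operative change in structural
    brain-network metrics plus clinical covariates. Builds streamline-count
    connectomes, performs virtual resection, log transform and cross-patient
    prevalence thresholding, computes weighted strength, betweenness centrality
    and clustering coefficient changes, harmonizes features across scanners,
    selects features with a SCAD-penalized least-squares path over a
    concavity-by-lambda grid inside nested leave-one-out cross-validation,
    classifies with a SMOTE-balanced linear support vector classifier, chains
    classifiers across follow-up timepoints, and assesses significance by
    permutation. Includes a synthetic cohort generator with planted effects for
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    igraph,
    e1071,
    sva,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
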