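Package: abprop
Title: Spatial Aggregation and Charge Descriptors for Antibody Variable
    Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes spatial aggregation propensity (SAP) and spatial
    charge map (SCM) descriptors over ten antibody variable-region domains
    (the six Chothia CDRs, the combined CDR, Hv, Lv and Fv) from atomic
    structures, including Shrake-Rupley solvent-accessible surface area,
    exposed-residue classification and ensemble statistics over structure
    snapshots. Also provides the sequence side of the workflow: Chothia
    template alignment and filtering of paired heavy/light variable-region
    sequences, fixed-size one-hot encoding, a one-dimensional convolutional
    neural network surrogate that predicts the thirty descriptors from
    sequence alone, and an exhaustive-feature-selection regression pipeline
    with leave-one-out cross-validation for modelling antibody aggregation
    rates from the descriptors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    randomForest,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
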