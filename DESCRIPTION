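Package: amypet
Title: Amyloid-PET Slice Classification with Block-Average Features and a
    Back-Propagation Network
Version: 0.1.0
Authors@R:
    person("amypet", "developers", email = "amypet@example.org",
           role = c("aut", "cre"))
Description: A two-stage pipeline for binary classification of 2D amyloid-PET
    brain slices. Stage one prepares images: automatic cropping of black
    frames, bilinear resizing to a fixed grid, and Average-Pixel-Per-Node
    (APPN) block-mean feature reduction to a normalized input vector. Stage
    two is a from-scratch three-layer back-propagation neural network with
    logistic-sigmoid activations, bias weights, momentum, and an RMS-error
    stopping rule, evaluated with a stratified hold-out protocol (sensitivity,
    specificity, accuracy per binary experiment). A synthetic phantom
    generator produces amyloid-PET-like elliptical slices with a graded
    cortical-rim uptake signal so the full pipeline can be exercised and
    tested without access to clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
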