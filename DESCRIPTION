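Package: eeginterp
Title: Interpretability Assessment of Convolutional EEG Decoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains compact convolutional neural networks (an EEGNet-style
    spatiotemporal network and a reduced residual network) to decode epoched
    multi-participant EEG under a participant-wise cross-validation protocol,
    extracts learned features with gradient attributions (saliency maps and
    Grad-CAM at early, intermediate, and late convolutional layers), and
    quantifies interpretability as the channel-wise Pearson correlation over
    time between aggregated attribution maps and the absolute amplitude of the
    averaged EEG, with one-sample Wilcoxon signed-rank tests against zero,
    Benjamini-Hochberg correction over time points, and paired Wilcoxon
    comparisons between networks, methods, and layers. A synthetic
    event-related-potential simulator with planted spatiotemporal components
    provides ground truth for validating every stage, and a surface Laplacian
    (spherical-spline current source density) renders topographies. Epoched
    data and attribution maps are stored in an HDF5 container.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    jsonlite,
    yaml,
    rhdf5,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
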