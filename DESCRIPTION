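Package: memodecode
Title: Encoding and Decoding of Hippocampal Memory Representations from
    Multi-Neuron Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the transformation of spatio-temporal spike
    patterns between hippocampal regions and for reading out binary memory
    categories from those patterns. Implements a sparse generalized
    Laguerre-Volterra multi-input multi-output (MIMO) point-process model
    that predicts output (CA1) spike trains from input (CA3) spike trains
    via probit-linked second-order Volterra kernels with group-LASSO
    selection of relevant inputs, and a B-spline feature-projection
    classifier with L1-penalized logistic regression that decodes left
    versus right memory events from single-trial spike patterns. Includes
    time-rescaling Kolmogorov-Smirnov goodness-of-fit assessment, a seeded
    generator of delayed-non-match-to-sample-like sessions with known
    ground truth, and an end-to-end pipeline that decodes memories from
    recorded inputs, recorded outputs, and model-predicted outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    glmnet,
    optparse,
    splines,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
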