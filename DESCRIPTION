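Package: pestnet
Title: Boundary-Aware Attention Networks for Fine-Grained Insect Pest Classification
Version: 0.1.0
Authors@R: person("pestnet", "developers", role = c("aut", "cre"),
    email = "pestnet@example.org")
Description: A self-contained implementation of a fine-grained insect-pest image
    classifier built around one-shot-aggregation (OSA) convolutional stages,
    boundary-aware channel-spatial attention with fixed Sobel edge priors,
    generalized p-norm pooling with a learnable exponent, a scheduled mixture of
    label-smoothed cross-entropy and focal loss, and growth-stage auxiliary label
    supervision (species classes split into developmental-stage subclasses during
    training and collapsed back at inference). Includes a procedural generator of
    stage-structured, long-tailed, cluttered insect-scene datasets, an evaluation
    toolkit (confusion matrix, macro/weighted F1, exact McNemar test), a training
    engine with warm-up and early stopping, and a command-line interface. All
    neural-network primitives (convolution, pooling, backpropagation, AdamW) are
    implemented natively; no external deep-learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    optparse,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
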