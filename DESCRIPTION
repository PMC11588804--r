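Package: hebbsdr
Title: Hebbian-Like RBM Learning Versus Backpropagation on Sparse
    Distributed Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation study comparing a Bernoulli restricted Boltzmann
    machine (RBM) joint classifier, trained with contrastive divergence or
    persistent contrastive divergence, against from-scratch backpropagation
    baselines (softmax logistic regression and a one-hidden-layer
    perceptron) on synthetic high-dimensional sparse two-Gaussian data.
    Provides the synthetic-data generator (generation, centering,
    per-sample sparsification, splitting, bit flipping, binarization), the
    RBM energy model with exact free-energy and Gibbs-sampling label
    prediction, mini-batch stochastic gradient descent networks with exact
    cross-entropy gradients, and a repeated-run experiment pipeline with
    sparsity sweeps, dimensionality-by-sparsity grids and a binary
    flip-probe, aggregating train/test accuracies over repetitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    data.table,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    jsonlite
Config/testthat/edition: 3
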