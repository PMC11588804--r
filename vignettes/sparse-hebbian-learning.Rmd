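---
title: "Hebbian-like RBM learning versus backpropagation on sparse distributed representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hebbian-like RBM learning versus backpropagation on sparse distributed representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hebbsdr)
```

## The question

Neocortical populations appear to encode information as sparse distributed
representations (SDRs): very high-dimensional binary patterns in which only
a small percentage of units are active. Classifying such patterns with
standard feed-forward networks runs into the curse of dimensionality — the
parameter count scales with the full input dimension, almost all of which
is zeros, and plain stochastic gradient descent happily memorizes the
training set while generalizing poorly.

A restricted Boltzmann machine (RBM) trained with contrastive divergence
updates each weight from the *correlation between its two endpoint units*:

$$\Delta w_{ij} \;=\; \eta\,\bigl(\langle v_j h_i\rangle^{0}_{\text{data}}
  - \langle v_j h_i\rangle^{\tau}_{\text{recon}}\bigr).$$

This rule is local and Hebbian-like, and it has a built-in asymmetry: a
visible unit with $v_j = 0$ contributes nothing to the correlation, so the
rule learns only from *active* units and ignores the zeros that make up
most of a sparse input. The package tests whether this asymmetry is enough
to escape the curse of dimensionality where backprop-trained networks
(logistic regression, and a one-hidden-layer perceptron with the same
hidden width as the RBM) overfit.

## Models

**RBM.** Bernoulli visible and hidden units with energy
$H(v,h) = -\sum_{ij} w_{ij} h_i v_j - \sum_j b_j v_j - \sum_i c_i h_i$ and
the usual factorial conditionals
$p(h_i{=}1\mid v) = \sigma(\sum_j w_{ij} v_j + c_i)$ and
$p(v_j{=}1\mid h) = \sigma(\sum_i w_{ij} h_i + b_j)$. For classification
the visible layer is the concatenation of the $d$ feature units and one
label unit, so the machine models the joint distribution of data and
label. Prediction clamps the features and either runs Gibbs sweeps over
(hidden, label) and averages the label-unit probability (`mode = "gibbs"`,
the pipeline's evaluation), or computes the exact posterior from the free
energies of the two label completions,
$F(v) = -b^\top v - \sum_i \log(1 + e^{\,c_i + (Wv)_i})$
(`mode = "exact"`). The two agree in distribution as the number of sweeps
grows; the exact mode doubles as an in-package oracle and both are checked
against brute-force enumeration in the tests.

**Backprop baselines.** `fit_backprop_net()` trains a softmax output layer
on the cross-entropy by plain mini-batch SGD — with `n_hidden = 0` this is
logistic regression; with a hidden layer of logistic-sigmoid units it is
the MLP. No momentum, weight decay, dropout or early stopping: the
overfitting behaviour of the unadorned algorithm is the object of study.
Gradients are exact (finite-difference-checked in the tests).

## The synthetic data

`generate_gaussian_dataset()` draws two equally sized classes from
multivariate normals: class 0 centred at the origin, class 1 at a vector
of fives, both with isotropic covariance
$\sigma^2 = \varepsilon\,\lVert \mu_1 - \mu_0\rVert$. The pipeline then
*centres* every feature (over the full dataset, before splitting),
*sparsifies* each sample independently by keeping a uniformly random
subset of $k = \mathrm{round}((1-s)d)$ features and zeroing the rest, and
splits 80/20. Sparsification after centring means a zero is exactly "no
information": the feature sits at the population mean.

The scale $\varepsilon$ controls problem difficulty and has no principled
closed-form value; it is anchored empirically. `calibrate_cov_scale()`
runs the dense 500-feature logistic-regression benchmark over a candidate
grid and picks the scale whose mean test accuracy is closest to the
~99% dense baseline. The package default is `cov_scale = 4`, which
reproduces both the dense baseline (within tolerance) and the sparse
overfitting benchmark; the calibration routine typically selects 3 on the
dense anchor alone, and both values are consistent with the published
behaviour of the benchmark.

What the generator deliberately does *not* emulate: feature correlations
(covariances are diagonal), class-dependent covariance, heavy tails, and
any spatial structure of real images. Passing tests on this data show that
the *learning-rule asymmetry* behaves as claimed under a clean
high-dimensional sparse geometry; they do not certify performance on real
sparse data, where correlated features could change both sides of the
comparison.

## Training the RBM on real-valued sparse data: a deliberate asymmetry

The generated features are real-valued and unbounded, while the Bernoulli
RBM's negative phase reconstructs visibles in $[0,1]$. Following the
design that the only Bernoulli-vs-Gaussian difference lies in the negative
phase, the positive phase clamps the centred, sparsified real values
*as-is*; negative-phase visibles are mean-field probabilities (hidden
units are sampled binary to drive the chain, probabilities enter the
correlation statistics). This bounds the reconstruction noise but has a
structural consequence: the data statistics
$\langle v_j h_i\rangle_{\text{data}}$ can be far outside anything the
$[0,1]$-bounded reconstruction can match, so the gradient never vanishes
and the weight norm grows steadily over training. Empirically the joint
classifier's accuracy plateaus after a few epochs and, with enough further
training, the growing weights make the model increasingly saturated and
prone to transient collapses.

Two defaults follow from this analysis:

* **Algorithm: CD-1, not PCD.** Persistent chains are a better gradient
  estimator when the model can actually match the data distribution. Here
  it cannot (by construction), and the fantasy chains drift into saturated
  corners far from the data manifold, destroying the label statistics.
  CD restarts every chain at the data, which anchors the negative phase
  and keeps the Hebbian correlation learning stable. Both algorithms are
  implemented and exported; `pcd_update()` carries its fantasy-chain state
  explicitly and is verified on an enumerable toy problem (total-variation
  distance to the data distribution decreases over training, where the
  model *is* well-specified).
* **Epochs: 20.** The classifier reaches its plateau well before 20
  epochs; beyond it the weight-norm growth only increases the risk of
  saturation-driven oscillation. Both the epoch count and the algorithm
  are ordinary `rbm_train_config()` fields.

Remaining training defaults mirror the study conditions: learning rate
0.1, batch size 50, 500 hidden units for the d = 5000 problems, $\tau = 1$
reconstruction steps, weights initialized N(0, 0.01²), biases 0. The nets
use the same learning rate, batch size, hidden width and initialization
(200 epochs, enough to drive their training accuracy to 100% on the sparse
problems). Prediction defaults are 100 Gibbs sweeps with 50 discarded, the
averaged label probability thresholded at 0.5, exact ties resolved to
class 1.

## The repeated-run pipeline

`run_pipeline()` repeats, for $r = 1..R$ (default 10): generate → centre →
sparsify → split → fit and evaluate each requested model, with every
random stage seeded from `base_seed + r` through fixed per-stage
sub-streams, so each model consumes independent randomness and removing
one model never perturbs the others. Accuracies are recorded in percent to
two decimals; means and standard deviations are recomputable from the
stored per-repetition values (asserted in the tests).
`sparsity_sweep()` and `dim_sparsity_grid()` hold everything fixed while
varying $s$ (default ladder 0.50–0.95) and $(d, s)$; the grid reports the
RBM − LR accuracy-difference surfaces. The full study-scale axes are
configurable; the shipped analysis scripts default to a reduced grid and
3–5 repetitions so a single-core run stays in the tens of minutes, and the
test suite uses a 3-repetition version of the MLP/RBM comparison for the
same reason.

## The bit-flip probe

`flip_probe()` makes the "ignores the zeros" mechanism visible without any
external image data. `generate_binary_patterns()` builds a desk-scale
stand-in for binarized digit images: 784 binary features, each class owns
a template of ~20% of the bits, half of that template shared between the
classes (as digit classes share the image centre), template bits firing
with probability 0.6 and background bits 0.05. Training and evaluating on
the patterns and on their bit-flipped complement encodes the *same
information* two ways: in the original code the class signal lives in
which units are ON; in the flipped code, in which are OFF. Logistic
regression treats ones and zeros symmetrically and should be essentially
indifferent to the flip, while the RBM should collapse on the flipped code
— its learning rule cannot see the informative zeros, and with ~85% of
units active the hidden layer saturates into a class-independent response.
The overlap and noise levels matter: with disjoint, nearly deterministic
templates the problem is so easy that every model solves both codes, and
the probe shows nothing.

## Numerical choices and degenerate inputs

* Sigmoids via `stats::plogis` and an overflow-safe softplus: conditionals
  and free energies stay finite for arbitrarily large weights.
* Mean-field negative-phase visibles (see above); hidden units always
  sampled binary to drive chains.
* Softmax logits are row-max-shifted before exponentiation.
* Exact ties: RBM posterior 0.5 → class 1; net argmax ties → higher class
  index (for two classes, the same threshold-0.5 rule).
* Degenerate requests error early: empty datasets, sparsity leaving zero
  kept features, splits with an empty part, non-binary input to
  `flip_bits()`, probabilities outside $[0,1]$.
* All training loops run in compiled code (RcppArmadillo) but draw from
  R's RNG in the same order as the exported R-level update operations, so
  fits are bit-reproducible from a seed and verifiable against
  `cd_update()` / `pcd_update()` / `net_gradients()` reference loops —
  the tests assert this equality to machine precision.

## Known limitations

* The generative model is idealized (independent features, equal isotropic
  class covariances); conclusions about the learning rules transfer to
  real SDRs only qualitatively.
* The joint classifier ships with a single label unit (two classes); the
  multi-class one-hot extension is not implemented.
* Under the real-valued clamping regime the RBM likelihood is improper, so
  "training to convergence" is not well-defined; defaults stop at the
  accuracy plateau, and very long training is known to oscillate.
* Gaussian-Bernoulli visible units are intentionally out of scope.
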