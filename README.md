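# hebbsdr

Can a Hebbian-like learning rule avoid the curse of dimensionality on
sparse distributed representations? `hebbsdr` is a simulation study that
puts that question to the test: it compares a Bernoulli restricted
Boltzmann machine (RBM) joint classifier, trained with the local
contrastive-divergence rule, against from-scratch backpropagation
baselines — softmax logistic regression (LR) and a one-hidden-layer
perceptron (MLP) — on synthetic high-dimensional sparse two-Gaussian data.

The package is aimed at computational-neuroscience and machine-learning
researchers who want a small, fully reproducible test bed for the claim
that a learning rule which *ignores zeros* generalizes where
backpropagation overfits.

## The core models

The RBM is an energy-based model over visible units `v` (the data plus one
label unit) and hidden units `h`:

    H(v, h) = - sum_ij w_ij h_i v_j - sum_j b_j v_j - sum_i c_i h_i

trained by contrastive divergence: with conditionals
`p(h_i = 1 | v) = sigma(sum_j w_ij v_j + c_i)` and
`p(v_j = 1 | h) = sigma(sum_i w_ij h_i + b_j)`, the weight update after a
tau-step reconstruction is the difference of local correlations

    dw_ij = eta * ( <v_j h_i>_data - <v_j h_i>_recon )

A visible unit at 0 contributes nothing to either correlation — the rule
learns only from active units. The baselines are trained by mini-batch
SGD on the cross-entropy, `dw = -eta * dE/dw`, with exact backprop
gradients; they treat ones and zeros alike.

Labels are predicted from the RBM either by Gibbs sampling with the
feature units clamped (averaging the label-unit probability over sweeps)
or exactly, from the free energies of the two label completions
`F(v) = -b.v - sum_i log(1 + exp(c_i + (W v)_i))`.

## What is in the box

* `R/` — the four building blocks, all exported and unit-tested against
  independent oracles (exhaustive Boltzmann enumeration, finite
  differences, hand-executed update traces):
  dataset generation / centring / sparsification / splitting / bit
  flipping (`dataset_spec`, `generate_gaussian_dataset`, ...), the RBM
  (`fit_rbm_classifier`, `cd_update`, `pcd_update`, `free_energy`,
  `predict`), the backprop nets (`fit_backprop_net`, `net_gradients`,
  ...), and the repeated-run experiment pipeline (`run_pipeline`,
  `sparsity_sweep`, `dim_sparsity_grid`, `flip_probe`, `report`).
* `analysis/` — numbered driver scripts reproducing the study end to end:
  `01_dense_vs_sparse.R` (LR on dense vs sparse data),
  `02_sparsity_sweep.R` (LR vs RBM across sparsity),
  `03_dim_sparsity_grid.R` (RBM−LR accuracy surfaces),
  `04_mlp_vs_rbm.R` (the learning-rule comparison at matched
  architecture), `05_flip_probe.R` (the bit-flip probe). Each writes tidy
  CSVs under `results/`.
* `vignettes/sparse-hebbian-learning.Rmd` — the methods notes: model
  definitions, generator calibration, why the pipeline RBM uses CD-1 and
  20 epochs, numerical choices, limitations.

## A worked example

Ten-repetition logistic-regression benchmark on the dense problem
(d = 500, no sparsification) versus the high-dimensional sparse one
(d = 5000, 95% of features zeroed per sample):

```r
library(hebbsdr)

dense <- run_pipeline(pipeline_config(
  dataset = dataset_spec(n_samples = 2000, n_features = 500, sparsity = 0,
                         cov_scale = 3),
  models = "LR", repetitions = 10, base_seed = 1))
dense
#> experiment_result: d = 500, sparsity = 0, 10 repetition(s)
#>   LR   train 100.00% (sd  0.00)   test  98.95% (sd  0.39)

sparse <- run_pipeline(pipeline_config(
  dataset = dataset_spec(n_samples = 2000, n_features = 5000,
                         sparsity = 0.95),
  models = "LR", repetitions = 10, base_seed = 1))
sparse
#> experiment_result: d = 5000, sparsity = 0.95, 10 repetition(s)
#>   LR   train 100.00% (sd  0.00)   test  66.12% (sd  2.29)
```

Read: on dense data LR generalizes almost perfectly (~99% test accuracy),
but on the sparse high-dimensional problem it memorizes the training set
(100%) while test accuracy collapses into the mid-60s — textbook curse of
dimensionality. Running the matched-architecture comparison
(`analysis/04_mlp_vs_rbm.R`) on the same sparse problem shows the MLP
behaving like LR (100% train, mid-60s test) while the RBM's train and test
accuracies sit close together in the mid-70s: the generalization advantage
comes from the Hebbian-like rule, not from having a hidden layer.

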