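# Independent oracles used across the test files.

# All 2^k binary vectors as rows (k small).
enum_binary <- function(k) {
  as.matrix(expand.grid(rep(list(c(0, 1)), k)))
}

# Exhaustive Boltzmann enumeration of a small RBM: unnormalized weight of
# every joint (v, h) state via the energy function, summed as needed.
# Everything is computed with plain loops and exp(-energy), independently of
# the package's conditional/free-energy code paths.
enum_rbm <- function(params) {
  m <- ncol(params$W)
  n <- nrow(params$W)
  vs <- enum_binary(m)
  hs <- enum_binary(n)
  wt <- matrix(0, nrow(vs), nrow(hs))
  for (a in seq_len(nrow(vs))) {
    for (b in seq_len(nrow(hs))) {
      e <- 0
      for (i in seq_len(n)) {
        for (j in seq_len(m)) {
          e <- e - params$W[i, j] * hs[b, i] * vs[a, j]
        }
      }
      e <- e - sum(params$b * vs[a, ]) - sum(params$c * hs[b, ])
      wt[a, b] <- exp(-e)
    }
  }
  list(vs = vs, hs = hs, wt = wt)
}

# P(h_i = 1 | v) by enumeration over hidden states.
enum_hidden_conditional <- function(params, v) {
  hs <- enum_binary(nrow(params$W))
  w <- apply(hs, 1L, function(h) exp(-energy(params, v, h)))
  unname(colSums(hs * w) / sum(w))
}

# P(v_j = 1 | h) by enumeration over visible states.
enum_visible_conditional <- function(params, h) {
  vs <- enum_binary(ncol(params$W))
  w <- apply(vs, 1L, function(v) exp(-energy(params, v, h)))
  unname(colSums(vs * w) / sum(w))
}

# P(label = 1 | features) for a joint RBM whose last visible unit is the
# label, by enumeration over the label and all hidden states.
enum_label_posterior <- function(params, x) {
  hs <- enum_binary(nrow(params$W))
  w_for <- function(lab) {
    v <- c(x, lab)
    sum(apply(hs, 1L, function(h) exp(-energy(params, v, h))))
  }
  w1 <- w_for(1)
  w0 <- w_for(0)
  w1 / (w0 + w1)
}

# Marginal P(v) of a small RBM by full enumeration.
enum_visible_marginal <- function(params) {
  e <- enum_rbm(params)
  p <- rowSums(e$wt)
  p / sum(p)
}

# Central finite differences of the mean cross-entropy w.r.t. every
# parameter of a backprop net.
fd_gradients <- function(params, X, y, h = 1e-5) {
  lapply(seq_along(params$layers), function(l) {
    gW <- params$layers[[l]]$W
    for (k in seq_along(gW)) {
      up <- params; up$layers[[l]]$W[k] <- up$layers[[l]]$W[k] + h
      dn <- params; dn$layers[[l]]$W[k] <- dn$layers[[l]]$W[k] - h
      gW[k] <- (net_loss(up, X, y) - net_loss(dn, X, y)) / (2 * h)
    }
    gb <- params$layers[[l]]$b
    for (k in seq_along(gb)) {
      up <- params; up$layers[[l]]$b[k] <- up$layers[[l]]$b[k] + h
      dn <- params; dn$layers[[l]]$b[k] <- dn$layers[[l]]$b[k] - h
      gb[k] <- (net_loss(up, X, y) - net_loss(dn, X, y)) / (2 * h)
    }
    list(W = gW, b = gb)
  })
}

# Small random RBM with moderate weights.
random_rbm <- function(n_visible, n_hidden, n_label_units = 0L, seed = 1L,
                       scale = 1) {
  p <- rbm_params(n_visible, n_hidden, n_label_units, seed = seed)
  set.seed(seed + 500L)
  p$W <- matrix(stats::rnorm(n_hidden * n_visible, sd = scale),
                n_hidden, n_visible)
  p$b <- stats::rnorm(n_visible, sd = scale)
  p$c <- stats::rnorm(n_hidden, sd = scale)
  p
}

# Tiny centered two-Gaussian dataset for fit smoke tests.
tiny_dataset <- function(n = 60L, d = 12L, cov_scale = 1, sparsity = 0,
                         seed = 7L) {
  spec <- dataset_spec(n_samples = n, n_features = d, cov_scale = cov_scale,
                       sparsity = sparsity, seed = seed)
  ds <- center_features(generate_gaussian_dataset(spec))
  if (sparsity > 0) ds <- sparsify(ds, sparsity, seed + 1L)
  ds
}
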