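#' Restricted Boltzmann machine parameters
#'
#' A Bernoulli-unit RBM over m visible and n hidden units with energy
#' \deqn{H(v, h) = -\sum_{i,j} w_{ij} h_i v_j - \sum_j b_j v_j
#'   - \sum_i c_i h_i.}
#' When the RBM is used as a joint classifier the last `n_label_units`
#' visible units encode the class label (one unit for two classes).
#'
#' @param n_visible,n_hidden layer sizes.
#' @param n_label_units how many trailing visible units encode the label
#'   (0 for a plain generative RBM).
#' @param init_sd standard deviation of the zero-mean Gaussian weight
#'   initialization; biases start at zero.
#' @param seed integer seed for the initialization draw.
#' @return an object of class `rbm_params` with fields `W`
#'   (n_hidden x n_visible), `b` (visible bias), `c` (hidden bias) and
#'   `n_label_units`.
#' @export
rbm_params <- function(n_visible, n_hidden, n_label_units = 0L,
                       init_sd = 0.01, seed = 1L) {
  stopifnot_scalar_number(n_visible, "n_visible")
  stopifnot_scalar_number(n_hidden, "n_hidden")
  n_visible <- as.integer(n_visible)
  n_hidden <- as.integer(n_hidden)
  n_label_units <- as.integer(n_label_units)
  if (n_visible < 1L || n_hidden < 1L) {
    stop("layer sizes must be positive", call. = FALSE)
  }
  if (n_label_units < 0L || n_label_units >= n_visible) {
    stop("`n_label_units` must be in [0, n_visible)", call. = FALSE)
  }
  set.seed(seed)
  structure(
    list(W = matrix(stats::rnorm(n_hidden * n_visible, sd = init_sd),
                    n_hidden, n_visible),
         b = numeric(n_visible),
         c = numeric(n_hidden),
         n_label_units = n_label_units),
    class = "rbm_params"
  )
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("rbm_params: %d visible (%d label) x %d hidden\n",
              ncol(x$W), x$n_label_units, nrow(x$W)))
  invisible(x)
}

#' Training configuration for an RBM
#'
#' @param learning_rate positive step size eta (default 0.1).
#' @param batch_size mini-batch size (default 50).
#' @param epochs full passes over the training set (default 20; the joint
#'   classifier plateaus well before that and very long training risks the
#'   weight-growth oscillations discussed in the vignette).
#' @param cd_steps number of alternating Gibbs steps tau in the negative
#'   phase (default 1).
#' @param algorithm `"CD"` (chains restarted at the data every update; the
#'   stable default for clamped real-valued inputs) or `"PCD"` (persistent
#'   fantasy chains).
#' @param seed integer seed controlling initialization, shuffling and all
#'   sampling during training.
#' @return an object of class `rbm_train_config`.
#' @export
rbm_train_config <- function(learning_rate = 0.1, batch_size = 50L,
                             epochs = 20L, cd_steps = 1L,
                             algorithm = c("CD", "PCD"), seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("`learning_rate` must be positive",
                               call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be positive", call. = FALSE)
  if (epochs < 0L) stop("`epochs` must be non-negative", call. = FALSE)
  if (cd_steps < 1L) stop("`cd_steps` (tau) must be at least 1",
                          call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 cd_steps = as.integer(cd_steps),
                 algorithm = algorithm,
                 seed = as.integer(seed)),
            class = "rbm_train_config")
}

#' RBM energy of a joint configuration
#'
#' @param params an [rbm_params()].
#' @param v visible vector (length n_visible).
#' @param h hidden binary vector (length n_hidden).
#' @return the scalar energy
#'   -sum_ij w_ij h_i v_j - sum_j b_j v_j - sum_i c_i h_i.
#' @export
energy <- function(params, v, h) {
  stopifnot(inherits(params, "rbm_params"))
  if (length(v) != ncol(params$W) || length(h) != nrow(params$W)) {
    stop("dimension mismatch between parameters and state vectors",
         call. = FALSE)
  }
  -as.numeric(h %*% params$W %*% v) - sum(params$b * v) - sum(params$c * h)
}

#' Conditional activation probabilities of one layer given the other
#'
#' `hidden_conditional` returns p(h_i = 1 | v) = sigma(W v + c)_i;
#' `visible_conditional` returns p(v_j = 1 | h) = sigma(W' h + b)_j.
#' Thanks to the bipartite structure each unit is conditionally independent
#' of its layer mates, so both are single guarded-sigmoid evaluations.
#'
#' @param params an [rbm_params()].
#' @param v visible vector; @param h hidden binary vector.
#' @return probability vector, every entry in (0, 1) for finite parameters.
#' @export
hidden_conditional <- function(params, v) {
  stopifnot(inherits(params, "rbm_params"))
  if (length(v) != ncol(params$W)) stop("dimension mismatch", call. = FALSE)
  sigmoid(as.numeric(params$W %*% v) + params$c)
}

#' @rdname hidden_conditional
#' @export
visible_conditional <- function(params, h) {
  stopifnot(inherits(params, "rbm_params"))
  if (length(h) != nrow(params$W)) stop("dimension mismatch", call. = FALSE)
  sigmoid(as.numeric(crossprod(params$W, h)) + params$b)
}

#' Independent Bernoulli draws
#'
#' Draws from the current R random stream, preserving matrix shape.
#'
#' @param p probabilities in \[0, 1\] (vector or matrix).
#' @return binary object of the same shape.
#' @export
sample_bernoulli <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]",
                               call. = FALSE)
  out <- (stats::runif(length(p)) < p) * 1
  if (is.matrix(p)) dim(out) <- dim(p)
  out
}

# batch-layer activations: rows are samples -----------------------------------

hidden_probs_batch <- function(params, V) {
  sigmoid(sweep(tcrossprod(V, params$W), 2L, params$c, `+`))
}

visible_probs_batch <- function(params, H) {
  sigmoid(sweep(H %*% params$W, 2L, params$b, `+`))
}

# One contrastive-divergence gradient evaluation. Positive statistics come
# from the clamped batch with hidden *probabilities*; the chain is driven by
# binary hidden samples, and negative-phase visibles use mean-field
# probability values (no visible sampling noise). `chain_v = NULL` restarts
# the chain at the data (CD); otherwise the persistent chain state is
# advanced and returned (PCD).
rbm_cd_stats <- function(params, batch, cd_steps, chain_v = NULL) {
  nb <- nrow(batch)
  h0p <- hidden_probs_batch(params, batch)
  if (is.null(chain_v)) {
    hs <- sample_bernoulli(h0p)
    for (t in seq_len(cd_steps)) {
      vk <- visible_probs_batch(params, hs)
      hkp <- hidden_probs_batch(params, vk)
      if (t < cd_steps) hs <- sample_bernoulli(hkp)
    }
  } else {
    vk <- chain_v
    for (t in seq_len(cd_steps)) {
      hs <- sample_bernoulli(hidden_probs_batch(params, vk))
      vk <- visible_probs_batch(params, hs)
    }
    hkp <- hidden_probs_batch(params, vk)
  }
  nc <- nrow(vk)
  list(
    dW = crossprod(h0p, batch) / nb - crossprod(hkp, vk) / nc,
    db = colMeans(batch) - colMeans(vk),
    dc = colMeans(h0p) - colMeans(hkp),
    chain_v = vk,
    chain_h = hs
  )
}

#' One contrastive-divergence parameter update
#'
#' Computes the CD-tau update for one mini-batch: positive correlations
#' <v_j h_i> from the clamped data, negative correlations from tau
#' alternating Gibbs steps started at the data, and applies
#' dW = eta (<v h>_data - <v h>_recon) together with the matching bias
#' updates, all averaged over the batch. Consumes the current R random
#' stream; seed it with `set.seed()` for reproducibility.
#'
#' @param params an [rbm_params()].
#' @param batch matrix of visible configurations, one row per sample.
#' @param config an [rbm_train_config()] (only `learning_rate` and
#'   `cd_steps` are used here).
#' @return the updated `rbm_params`.
#' @export
cd_update <- function(params, batch, config) {
  stopifnot(inherits(params, "rbm_params"),
            inherits(config, "rbm_train_config"))
  if (!is.matrix(batch) || nrow(batch) == 0L) {
    stop("`batch` must be a non-empty matrix", call. = FALSE)
  }
  if (ncol(batch) != ncol(params$W)) stop("dimension mismatch", call. = FALSE)
  g <- rbm_cd_stats(params, batch, config$cd_steps)
  params$W <- params$W + config$learning_rate * g$dW
  params$b <- params$b + config$learning_rate * g$db
  params$c <- params$c + config$learning_rate * g$dc
  params
}

#' One persistent contrastive-divergence update
#'
#' Identical positive phase to [cd_update()], but the negative statistics
#' come from advancing a set of persistent fantasy chains tau steps from
#' their previous state instead of restarting them at the data. On the very
#' first update, with chains initialized at the batch, the result coincides
#' with [cd_update()].
#'
#' @inheritParams cd_update
#' @param chains list with element `v` (fantasy visible states, one row per
#'   chain), as returned by this function or initialized from a data batch.
#' @return list with the updated `params` and the advanced `chains`
#'   (elements `v` and `h`).
#' @export
pcd_update <- function(params, batch, chains, config) {
  stopifnot(inherits(params, "rbm_params"),
            inherits(config, "rbm_train_config"))
  if (!is.matrix(batch) || nrow(batch) == 0L) {
    stop("`batch` must be a non-empty matrix", call. = FALSE)
  }
  if (ncol(batch) != ncol(params$W) || ncol(chains$v) != ncol(params$W)) {
    stop("dimension mismatch", call. = FALSE)
  }
  g <- rbm_cd_stats(params, batch, config$cd_steps, chain_v = chains$v)
  params$W <- params$W + config$learning_rate * g$dW
  params$b <- params$b + config$learning_rate * g$db
  params$c <- params$c + config$learning_rate * g$dc
  list(params = params, chains = list(v = g$chain_v, h = g$chain_h))
}

#' Train a joint RBM classifier
#'
#' Concatenates the feature columns with one trailing label unit, so the
#' RBM models the joint distribution of data and label, and trains it by
#' mini-batch CD or PCD. Labels are clamped as part of the visible data in
#' the positive phase. Real-valued (centred, sparsified) features are
#' clamped as-is; the Bernoulli structure enters only when the negative
#' phase recomputes the visibles as probabilities in \[0, 1\].
#'
#' @param train a `labeled_dataset` with binary labels.
#' @param n_hidden number of hidden units (default 500).
#' @param config an [rbm_train_config()].
#' @param init_sd weight initialization standard deviation.
#' @return an `rbm_params` with `n_label_units = 1`.
#' @export
fit_rbm_classifier <- function(train, n_hidden = 500L,
                               config = rbm_train_config(),
                               init_sd = 0.01) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(config, "rbm_train_config"))
  if (n_hidden < 1L) stop("`n_hidden` must be positive", call. = FALSE)
  if (!is_binary(train$labels)) stop("labels must be binary", call. = FALSE)
  V <- cbind(train$features, as.numeric(train$labels))
  n <- nrow(V)
  params <- rbm_params(ncol(V), n_hidden, n_label_units = 1L,
                       init_sd = init_sd, seed = config$seed)
  if (config$epochs == 0L) return(params)
  # separate sub-stream for shuffling/sampling so it does not replay the
  # initialization draws; the compiled loop consumes R's RNG in the same
  # order as a cd_update()/pcd_update() driven loop would
  set.seed(derive_seed(config$seed, 7L))
  state <- list(W = params$W, b = params$b, c = params$c, chain_v = NULL)
  chain <- NULL
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    state <- rbm_epoch_cpp(state$W, state$b, state$c, V, perm,
                           config$batch_size, config$learning_rate,
                           config$cd_steps, config$algorithm == "PCD",
                           chain)
    if (config$algorithm == "PCD") chain <- state$chain_v
  }
  params$W <- state$W
  params$b <- as.numeric(state$b)
  params$c <- as.numeric(state$c)
  params
}

#' Free energy of a visible configuration
#'
#' Analytic marginalization of the energy over the hidden layer:
#' F(v) = -b.v - sum_i log(1 + exp(c_i + (W v)_i)), so that
#' P(v) is proportional to exp(-F(v)). Evaluated with an overflow-safe
#' softplus.
#'
#' @param params an [rbm_params()].
#' @param v visible vector, or a matrix with one configuration per row.
#' @return scalar (or one value per row).
#' @export
free_energy <- function(params, v) {
  stopifnot(inherits(params, "rbm_params"))
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  if (ncol(v) != ncol(params$W)) stop("dimension mismatch", call. = FALSE)
  act <- sweep(v %*% t(params$W), 2L, params$c, `+`)
  f <- -as.numeric(v %*% params$b) - rowSums(softplus(act))
  if (length(f) == 1L) f[[1L]] else f
}

#' Predict class labels with a joint RBM
#'
#' In `"gibbs"` mode the feature units are clamped at every sweep while the
#' hidden units and the label unit are resampled; the reported label is the
#' mean label-unit probability over the post-burn-in sweeps, thresholded at
#' 0.5 (ties go to class 1). In `"exact"` mode the label posterior is
#' computed in closed form from the free energies of the two label
#' completions, P(y = 1 | x) = sigma(F(x, 0) - F(x, 1)); the two modes agree
#' in distribution as the number of sweeps grows.
#'
#' @param object an `rbm_params` with one label unit.
#' @param X feature matrix (no label column), one sample per row.
#' @param mode `"gibbs"` or `"exact"`.
#' @param n_gibbs total Gibbs sweeps per sample (gibbs mode).
#' @param burn_in sweeps discarded before averaging; must be < `n_gibbs`.
#' @param posterior if `TRUE`, return P(y = 1 | x) instead of hard labels.
#' @param ... unused.
#' @return integer labels in \{0, 1\} (or posterior probabilities).
#' @export
predict.rbm_params <- function(object, X, mode = c("gibbs", "exact"),
                               n_gibbs = 100L, burn_in = 50L,
                               posterior = FALSE, ...) {
  mode <- match.arg(mode)
  if (object$n_label_units != 1L) {
    stop("prediction requires an RBM with exactly one label unit",
         call. = FALSE)
  }
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  m <- ncol(object$W)
  if (ncol(X) != m - 1L) {
    stop("feature count must equal n_visible - n_label_units",
         call. = FALSE)
  }
  w_lab <- object$W[, m]
  b_lab <- object$b[m]
  # hidden pre-activations from the clamped features, computed once
  base <- sweep(tcrossprod(X, object$W[, -m, drop = FALSE]), 2L, object$c,
                `+`)
  if (mode == "exact") {
    f0 <- -as.numeric(X %*% object$b[-m]) - rowSums(softplus(base))
    f1 <- f0 - b_lab -
      rowSums(softplus(sweep(base, 2L, w_lab, `+`))) + rowSums(softplus(base))
    p1 <- sigmoid(f0 - f1)
  } else {
    if (n_gibbs <= burn_in) stop("`n_gibbs` must exceed `burn_in`",
                                 call. = FALSE)
    n <- nrow(X)
    v_lab <- rep(0.5, n)
    acc <- numeric(n)
    for (sweep_i in seq_len(n_gibbs)) {
      hp <- sigmoid(base + outer(v_lab, w_lab))
      hs <- sample_bernoulli(hp)
      p_lab <- sigmoid(as.numeric(hs %*% w_lab) + b_lab)
      v_lab <- sample_bernoulli(p_lab)
      if (sweep_i > burn_in) acc <- acc + p_lab
    }
    p1 <- acc / (n_gibbs - burn_in)
  }
  if (posterior) return(p1)
  as.integer(p1 >= 0.5)
}

#' Save / load RBM or network parameters
#'
#' Writes a self-describing container (shapes, arrays, a config echo) that
#' round-trips losslessly through `readRDS`.
#'
#' @param params an `rbm_params` or `backprop_net`.
#' @param path file path; @param config optional training config to echo.
#' @return `save_params` returns `path` invisibly; `load_params` the object.
#' @export
save_params <- function(params, path, config = NULL) {
  saveRDS(list(container = "hebbsdr_params", version = 1L,
               class = class(params), params = unclass(params),
               config = config),
          path)
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  obj <- readRDS(path)
  stopifnot(identical(obj$container, "hebbsdr_params"))
  structure(obj$params, class = obj$class)
}
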