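#' Training configuration for the backprop networks
#'
#' @param learning_rate positive SGD step size eta (default 0.1, matching
#'   the RBM for a fair comparison).
#' @param batch_size mini-batch size (default 50).
#' @param epochs full passes over the training set (default 200, enough for
#'   the overparameterized nets to drive training accuracy to 100% on the
#'   sparse problems).
#' @param seed integer seed; initialization uses it directly and the
#'   shuffle of epoch e is re-seeded with `seed + e`.
#' @return an object of class `net_train_config`.
#' @export
net_train_config <- function(learning_rate = 0.1, batch_size = 50L,
                             epochs = 200L, seed = 1L) {
  stopifnot_scalar_number(learning_rate, "learning_rate")
  if (learning_rate <= 0) stop("`learning_rate` must be positive",
                               call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be positive", call. = FALSE)
  if (epochs < 0L) stop("`epochs` must be non-negative", call. = FALSE)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 seed = as.integer(seed)),
            class = "net_train_config")
}

#' Initialize a softmax network
#'
#' `n_hidden = 0` gives plain (multinomial) logistic regression: a single
#' affine layer into a softmax. `n_hidden > 0` inserts one hidden layer of
#' logistic-sigmoid units. Weights are zero-mean Gaussian with standard
#' deviation `init_sd`; biases start at zero.
#'
#' @param n_features input dimensionality.
#' @param n_hidden hidden-layer width, 0 for logistic regression.
#' @param n_classes number of output classes (default 2).
#' @param init_sd weight initialization standard deviation.
#' @param seed integer seed.
#' @return an object of class `backprop_net`: a list of layers, each with
#'   weight matrix `W` (inputs x outputs) and bias vector `b`.
#' @export
net_init <- function(n_features, n_hidden = 0L, n_classes = 2L,
                     init_sd = 0.01, seed = 1L) {
  if (n_features < 1L || n_classes < 2L || n_hidden < 0L) {
    stop("invalid architecture", call. = FALSE)
  }
  set.seed(seed)
  dims <- if (n_hidden > 0L) c(n_features, n_hidden, n_classes) else
    c(n_features, n_classes)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(dims[l] * dims[l + 1L], sd = init_sd),
                 dims[l], dims[l + 1L]),
      b = numeric(dims[l + 1L])
    )
  }
  structure(list(layers = layers,
                 n_hidden = as.integer(n_hidden),
                 n_classes = as.integer(n_classes)),
            class = "backprop_net")
}

#' @export
print.backprop_net <- function(x, ...) {
  arch <- if (x$n_hidden > 0L) {
    sprintf("MLP %d-%d-%d (sigmoid hidden)", nrow(x$layers[[1]]$W),
            x$n_hidden, x$n_classes)
  } else {
    sprintf("logistic regression %d-%d", nrow(x$layers[[1]]$W), x$n_classes)
  }
  cat("backprop_net:", arch, "\n")
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass keeping hidden activations for the backward phase
net_forward_full <- function(params, X) {
  a <- X
  hidden <- NULL
  n_layers <- length(params$layers)
  if (n_layers == 2L) {
    l1 <- params$layers[[1L]]
    hidden <- sigmoid(sweep(a %*% l1$W, 2L, l1$b, `+`))
    a <- hidden
  }
  lo <- params$layers[[n_layers]]
  probs <- softmax_rows(sweep(a %*% lo$W, 2L, lo$b, `+`))
  list(probs = probs, hidden = hidden)
}

#' Forward pass: class probabilities
#'
#' Propagates inputs through the (zero- or one-hidden-layer) network and
#' returns the softmax output; every row sums to 1.
#'
#' @param params a [net_init()] / [fit_backprop_net()] object.
#' @param X feature matrix, one sample per row.
#' @return n x n_classes probability matrix.
#' @export
net_forward <- function(params, X) {
  stopifnot(inherits(params, "backprop_net"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != nrow(params$layers[[1L]]$W)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  net_forward_full(params, X)$probs
}

#' Exact gradients of the mean cross-entropy
#'
#' Backpropagation through the softmax output (and the sigmoid hidden layer
#' when present). The returned structure mirrors the layer list, so
#' `params$layers[[l]]$W - eta * grad[[l]]$W` is the SGD update.
#'
#' @param params a `backprop_net`.
#' @param X feature matrix; @param y integer labels in 0:(n_classes-1).
#' @return list of per-layer gradients (`W`, `b`) of the mean cross-entropy.
#' @export
net_gradients <- function(params, X, y) {
  stopifnot(inherits(params, "backprop_net"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) != length(y)) stop("dimension mismatch", call. = FALSE)
  n <- nrow(X)
  fwd <- net_forward_full(params, X)
  Y <- matrix(0, n, params$n_classes)
  Y[cbind(seq_len(n), y + 1L)] <- 1
  delta <- (fwd$probs - Y) / n          # d(mean CE)/d(logits)
  n_layers <- length(params$layers)
  grads <- vector("list", n_layers)
  a_in <- if (n_layers == 2L) fwd$hidden else X
  grads[[n_layers]] <- list(W = crossprod(a_in, delta), b = colSums(delta))
  if (n_layers == 2L) {
    dh <- (delta %*% t(params$layers[[2L]]$W)) * fwd$hidden * (1 - fwd$hidden)
    grads[[1L]] <- list(W = crossprod(X, dh), b = colSums(dh))
  }
  grads
}

#' Mean cross-entropy loss
#'
#' @param params a `backprop_net`; @param X features; @param y labels.
#' @return scalar mean negative log-likelihood of the true classes.
#' @export
net_loss <- function(params, X, y) {
  p <- net_forward(params, X)
  idx <- cbind(seq_along(y), y + 1L)
  -mean(log(pmax(p[idx], .Machine$double.xmin)))
}

#' Train a network by plain mini-batch SGD
#'
#' Update rule: w <- w - eta * d(mean batch cross-entropy)/dw. No momentum,
#' regularization or early stopping — the overfitting behaviour of the plain
#' algorithm is the object of study.
#'
#' @param train a `labeled_dataset` with binary labels.
#' @param n_hidden hidden width; 0 trains logistic regression.
#' @param config a [net_train_config()].
#' @param init_sd weight initialization standard deviation.
#' @return a fitted `backprop_net`.
#' @export
fit_backprop_net <- function(train, n_hidden = 0L,
                             config = net_train_config(),
                             init_sd = 0.01) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(config, "net_train_config"))
  if (!is_binary(train$labels)) stop("labels must be in {0, 1}",
                                     call. = FALSE)
  X <- train$features
  y <- train$labels
  n <- nrow(X)
  if (n == 0L) stop("empty training set", call. = FALSE)
  params <- net_init(ncol(X), n_hidden, n_classes = 2L,
                     init_sd = init_sd, seed = config$seed)
  if (config$epochs == 0L) return(params)
  # compiled SGD kernel; epoch e reshuffles with set.seed(seed + e),
  # matching a net_gradients() driven reference loop exactly
  layers <- params$layers
  for (epoch in seq_len(config$epochs)) {
    set.seed(config$seed + epoch)
    perm <- sample.int(n)
    layers <- net_epoch_cpp(layers, X, as.integer(y), perm,
                            config$batch_size, config$learning_rate)
  }
  params$layers <- lapply(layers, function(l) {
    list(W = l$W, b = as.numeric(l$b))
  })
  params
}

#' Predict hard labels with a backprop network
#'
#' Argmax of the forward probabilities; exact ties resolve to the higher
#' class index (for two classes this is the threshold-0.5 rule on
#' P(class 1)).
#'
#' @param object a `backprop_net`; @param X feature matrix; @param ... unused.
#' @return integer labels in 0:(n_classes-1).
#' @export
predict.backprop_net <- function(object, X, ...) {
  p <- net_forward(object, X)
  max.col(p, ties.method = "last") - 1L
}
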