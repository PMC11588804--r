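#' Numerically guarded logistic sigmoid
#'
#' `stats::plogis` evaluates 1/(1+exp(-x)) without overflow for any finite
#' input, so extreme weights (|w| >> 50) still give probabilities in
#' \[0, 1\] rather than NaN.
#'
#' @param x numeric vector or matrix of logits.
#' @return object of the same shape with values in (0, 1) (0/1 only at
#'   infinite input).
#' @keywords internal
sigmoid <- function(x) {
  stats::plogis(x)
}

#' Overflow-safe softplus, log(1 + exp(x))
#'
#' For large positive x, log1p(exp(x)) overflows; there softplus(x) = x to
#' double precision (the switch at 35 is far past the 1e-16 crossover).
#'
#' @param x numeric vector or matrix.
#' @return same shape, elementwise log(1 + exp(x)).
#' @keywords internal
softplus <- function(x) {
  out <- x
  low <- x <= 35
  out[low] <- log1p(exp(x[low]))
  out
}

# Derive a reproducible sub-stream seed from a base seed and a stage/model
# index, kept inside the 32-bit integer range. Distinct (seed, k) pairs map
# to distinct streams so that adding or removing a model in the pipeline
# does not perturb the randomness the other models consume.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 104729) %% 2147483647L)
}

# shared argument checks ----------------------------------------------------

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
}

is_binary <- function(x) {
  all(x %in% c(0, 1))
}
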