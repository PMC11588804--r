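#' Generate dense binary patterns with class-correlated active bits
#'
#' Synthetic stand-in for binarized image data: each class owns a random
#' template of `round(active_frac * n_features)` "figure" bits, drawn once
#' per dataset. A sample of class c activates template bits with
#' probability `p_active` and every other bit with probability
#' `p_background`, so the class signal lives in which bits are ON — the
#' structure the bit-flip probe inverts.
#'
#' @param n_samples total samples (first half class 0).
#' @param n_features pattern length.
#' @param active_frac fraction of bits in each class template.
#' @param p_active activation probability of template bits.
#' @param p_background activation probability of background bits.
#' @param template_overlap fraction of each template shared between the two
#'   classes (images of different classes share most of their ink area, so
#'   only the complement of the shared core is class-discriminative).
#' @param seed integer seed.
#' @return a binary `labeled_dataset` at stage `"raw"`.
#' @export
generate_binary_patterns <- function(n_samples = 2000L, n_features = 784L,
                                     active_frac = 0.2, p_active = 0.6,
                                     p_background = 0.05,
                                     template_overlap = 0.5, seed = 1L) {
  if (active_frac <= 0 || active_frac >= 1) {
    stop("`active_frac` must lie in (0, 1)", call. = FALSE)
  }
  if (template_overlap < 0 || template_overlap >= 1) {
    stop("`template_overlap` must lie in [0, 1)", call. = FALSE)
  }
  set.seed(seed)
  n0 <- n_samples %/% 2L
  labels <- c(rep(0L, n0), rep(1L, n_samples - n0))
  n_active <- max(1L, round(active_frac * n_features))
  n_core <- round(template_overlap * n_active)
  pool <- sample.int(n_features)
  core <- pool[seq_len(n_core)]
  rest <- pool[-seq_len(n_core)]
  spec0 <- rest[seq_len(n_active - n_core)]
  spec1 <- rest[(n_active - n_core + 1L):(2L * (n_active - n_core))]
  templates <- list(c(core, spec0), c(core, spec1))
  p <- matrix(p_background, n_samples, n_features)
  p[seq_len(n0), templates[[1L]]] <- p_active
  p[(n0 + 1L):n_samples, templates[[2L]]] <- p_active
  new_labeled_dataset(sample_bernoulli(p), labels, "raw")
}

#' Bit-flip probe: does the learner survive inverting the code?
#'
#' Trains logistic regression and the joint RBM classifier on a dense
#' binary pattern problem and on its bit-flipped complement (every 0
#' becomes 1 and vice versa — the same information, recoded so the class
#' signal sits in the zeros). Backprop treats both codes symmetrically,
#' while the RBM's Hebbian-like rule only learns correlations between
#' active units, so flipping should leave LR essentially unchanged and
#' degrade the RBM severely.
#'
#' @param n_samples,n_features,active_frac,p_active,p_background,template_overlap
#'   pattern generator settings, see [generate_binary_patterns()].
#' @param n_hidden hidden width for the RBM (default 100).
#' @param net_config,rbm_config training configurations.
#' @param repetitions independent repetitions (fresh data each time).
#' @param base_seed repetition seed anchor.
#' @param train_fraction train share of the split.
#' @return data.frame with one row per (model, version) giving mean train
#'   and test accuracies over repetitions, plus a `raw` attribute with the
#'   per-repetition values.
#' @export
flip_probe <- function(n_samples = 2000L, n_features = 784L,
                       active_frac = 0.2, p_active = 0.6,
                       p_background = 0.05, template_overlap = 0.5,
                       n_hidden = 100L,
                       net_config = net_train_config(),
                       rbm_config = rbm_train_config(),
                       repetitions = 3L, base_seed = 1L,
                       train_fraction = 0.8) {
  rows <- list()
  for (r in seq_len(repetitions)) {
    rep_seed <- base_seed + r
    ds <- generate_binary_patterns(n_samples, n_features, active_frac,
                                   p_active, p_background, template_overlap,
                                   seed = derive_seed(rep_seed, 1L))
    for (version in c("original", "flipped")) {
      feats <- if (version == "flipped") flip_bits(ds$features) else
        ds$features
      data <- new_labeled_dataset(feats, ds$labels, "raw")
      split <- train_test_split(data, train_fraction,
                                derive_seed(rep_seed, 3L))
      for (model in c("LR", "RBM")) {
        seed <- derive_seed(rep_seed, model_seed_slot[[model]])
        if (model == "LR") {
          cfg <- net_config
          cfg$seed <- seed
          fit <- fit_backprop_net(split$train, n_hidden = 0L, config = cfg)
          pred_train <- predict(fit, split$train$features)
          pred_test <- predict(fit, split$test$features)
        } else {
          cfg <- rbm_config
          cfg$seed <- seed
          fit <- fit_rbm_classifier(split$train, n_hidden = n_hidden,
                                    config = cfg)
          set.seed(derive_seed(rep_seed, 21L))
          pred_train <- predict(fit, split$train$features)
          pred_test <- predict(fit, split$test$features)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, version = version, repetition = r,
          train_acc = round(accuracy(pred_train, split$train$labels), 2),
          test_acc = round(accuracy(pred_test, split$test$labels), 2))
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(raw, list(raw$model, raw$version)),
    function(g) data.frame(model = g$model[1L], version = g$version[1L],
                           train_mean = mean(g$train_acc),
                           test_mean = mean(g$test_acc))))
  agg <- agg[order(agg$model, match(agg$version, c("original", "flipped"))), ]
  rownames(agg) <- NULL
  attr(agg, "raw") <- raw
  agg
}
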