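test_that("energy matches the bilinear definition", {
  p <- rbm_params(3L, 2L, seed = 1L)
  p$W[] <- 0
  expect_identical(energy(p, c(1, 0, 1), c(1, 1)), 0)

  p1 <- rbm_params(1L, 1L, seed = 1L)
  p1$W[] <- 2
  p1$b <- 0.5
  p1$c <- -1
  expect_equal(energy(p1, 1, 1), -1.5)

  # independent triple-loop evaluation
  p2 <- random_rbm(4L, 3L, seed = 2L)
  v <- c(1, 0, 1, 1)
  h <- c(0, 1, 1)
  e <- 0
  for (i in 1:3) for (j in 1:4) e <- e - p2$W[i, j] * h[i] * v[j]
  e <- e - sum(p2$b * v) - sum(p2$c * h)
  expect_equal(energy(p2, v, h), e, tolerance = 1e-12)

  expect_error(energy(p2, c(1, 0), h), "mismatch")
})

test_that("layer conditionals equal exhaustive Boltzmann enumeration", {
  p0 <- rbm_params(3L, 2L, seed = 3L)
  p0$W[] <- 0
  expect_equal(hidden_conditional(p0, c(1, 1, 0)), rep(0.5, 2L))
  expect_equal(visible_conditional(p0, c(1, 0)), rep(0.5, 3L))

  psat <- rbm_params(2L, 2L, seed = 4L)
  psat$W[] <- 0
  psat$c <- c(50, -50)
  pr <- hidden_conditional(psat, c(0, 0))
  expect_equal(pr[1L], 1, tolerance = 1e-15)
  expect_equal(pr[2L], 0, tolerance = 1e-15)

  for (seed in 1:5) {
    p <- random_rbm(3L, 2L, seed = seed)
    v <- enum_binary(3L)[sample.int(8L, 1L), ]
    h <- enum_binary(2L)[sample.int(4L, 1L), ]
    expect_equal(hidden_conditional(p, v), enum_hidden_conditional(p, v),
                 tolerance = 1e-10)
    expect_equal(visible_conditional(p, h), enum_visible_conditional(p, h),
                 tolerance = 1e-10)
  }
})

test_that("conditionals stay finite and in [0, 1] under extreme weights", {
  p <- random_rbm(5L, 4L, seed = 9L, scale = 50)
  v <- c(1, 0, 1, 1, 0)
  pr_h <- hidden_conditional(p, v)
  pr_v <- visible_conditional(p, c(1, 0, 1, 1))
  expect_true(all(is.finite(pr_h)) && all(pr_h >= 0 & pr_h <= 1))
  expect_true(all(is.finite(pr_v)) && all(pr_v >= 0 & pr_v <= 1))
  expect_true(all(is.finite(free_energy(p, v))))
})

test_that("Bernoulli sampling honours probabilities and the stream", {
  expect_identical(sample_bernoulli(c(0, 1, 0, 1)), c(0, 1, 0, 1))
  set.seed(5)
  draws <- sample_bernoulli(rep(0.3, 1e5))
  expect_lt(abs(mean(draws) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  set.seed(6)
  a <- sample_bernoulli(rep(0.5, 10))
  set.seed(6)
  b <- sample_bernoulli(rep(0.5, 10))
  expect_identical(a, b)
  expect_error(sample_bernoulli(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cd_update reproduces a hand-executed CD-1 trace", {
  # 2 visible, 1 hidden, one sample: follow conditionals -> sampling ->
  # reconstruction -> weight rule step by step with the same RNG stream
  p <- rbm_params(2L, 1L, seed = 7L)
  p$W[] <- c(0.4, -0.3)
  p$b <- c(0.1, 0.2)
  p$c <- 0.05
  v0 <- matrix(c(1, 0.5), 1L)
  cfg <- rbm_train_config(learning_rate = 0.2, cd_steps = 1L, seed = 1L,
                          algorithm = "CD")

  set.seed(8)
  h0p <- plogis(sum(p$W * v0) + p$c)
  h0s <- as.numeric(runif(1) < h0p)
  v1 <- plogis(as.numeric(p$W) * h0s + p$b)
  h1p <- plogis(sum(p$W * v1) + p$c)
  dW <- h0p %*% v0 - h1p %*% t(v1)
  db <- as.numeric(v0) - v1
  dc <- h0p - h1p

  set.seed(8)
  up <- cd_update(p, v0, cfg)
  expect_equal(up$W, p$W + 0.2 * dW, tolerance = 1e-12)
  expect_equal(up$b, p$b + 0.2 * db, tolerance = 1e-12)
  expect_equal(up$c, p$c + 0.2 * dc, tolerance = 1e-12)
})

test_that("the CD rule is antisymmetric in data and reconstruction statistics", {
  # Eq-level property: swapping the positive and negative phase statistics
  # negates every parameter increment
  set.seed(10)
  v0 <- matrix(runif(8), 2L)
  vk <- matrix(runif(8), 2L)
  h0 <- matrix(runif(6), 2L)
  hk <- matrix(runif(6), 2L)
  dW <- crossprod(h0, v0) / 2 - crossprod(hk, vk) / 2
  dW_swapped <- crossprod(hk, vk) / 2 - crossprod(h0, v0) / 2
  expect_equal(dW_swapped, -dW)
  # and when the two phases agree the update vanishes
  expect_equal(crossprod(h0, v0) / 2 - crossprod(h0, v0) / 2,
               matrix(0, 3L, 4L))
})

test_that("a visible unit at zero in both phases receives no weight update", {
  # column 2 of the data is all zeros and its bias is driven to -1000 so
  # the mean-field reconstruction is exactly 0 there: the Hebbian rule
  # never touches weights into a silent unit
  p <- random_rbm(3L, 4L, seed = 11L, scale = 0.5)
  p$b[2L] <- -1000
  batch <- cbind(runif(5), 0, runif(5))
  cfg <- rbm_train_config(learning_rate = 0.1, algorithm = "CD", seed = 1L)
  set.seed(12)
  up <- cd_update(p, batch, cfg)
  expect_identical(up$W[, 2L], p$W[, 2L])
  expect_identical(up$b[2L], p$b[2L])
  expect_false(identical(up$W[, 1L], p$W[, 1L]))
})

test_that("Hebbian locality: dw_ij only sees units i and j", {
  # with saturated hidden units the activities are deterministic, so
  # zeroing the other visible units must leave dw_11 unchanged
  base <- rbm_params(3L, 2L, seed = 13L)
  base$W <- matrix(c(80, 0, 0,
                     0, 80, 0), 2L, 3L, byrow = TRUE)
  base$b <- c(0, 0, -1000)
  cfg <- rbm_train_config(learning_rate = 0.1, algorithm = "CD", seed = 1L)
  batch_full <- matrix(c(1, 1, 0), 1L)
  batch_zeroed <- matrix(c(1, 0, 0), 1L)
  set.seed(14)
  up_full <- cd_update(base, batch_full, cfg)
  set.seed(14)
  up_zeroed <- cd_update(base, batch_zeroed, cfg)
  expect_equal(up_full$W[1L, 1L] - base$W[1L, 1L],
               up_zeroed$W[1L, 1L] - base$W[1L, 1L], tolerance = 1e-12)
})

test_that("PCD's first step from data-initialized chains is CD", {
  p <- random_rbm(4L, 3L, seed = 15L, scale = 0.3)
  batch <- matrix(runif(12), 3L)
  cfg <- rbm_train_config(learning_rate = 0.1, cd_steps = 2L, seed = 1L)
  set.seed(16)
  via_cd <- cd_update(p, batch, cfg)
  set.seed(16)
  via_pcd <- pcd_update(p, batch, list(v = batch), cfg)
  expect_equal(via_pcd$params$W, via_cd$W, tolerance = 1e-12)
  expect_equal(via_pcd$params$b, via_cd$b, tolerance = 1e-12)
  # and the chains have been advanced away from their start
  expect_false(identical(via_pcd$chains$v, batch))
})

test_that("PCD training shrinks the gap to the data distribution on a toy", {
  # 4 visible units, two patterns; total variation between the enumerated
  # model marginal and the empirical distribution must drop over training
  patterns <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  V <- patterns[rep(1:2, each = 20L), ]
  emp <- rep(0, 16L)
  key <- function(v) sum(v * 2^(0:3)) + 1L
  emp[key(patterns[1L, ])] <- 0.5
  emp[key(patterns[2L, ])] <- 0.5

  tv <- function(p) {
    marg <- enum_visible_marginal(p)
    idx <- apply(enum_rbm(p)$vs, 1L, key)
    0.5 * sum(abs(marg[order(idx)] - emp))
  }

  p <- rbm_params(4L, 2L, seed = 17L)
  tv0 <- tv(p)
  cfg <- rbm_train_config(learning_rate = 0.1, batch_size = 10L,
                          epochs = 80L, algorithm = "PCD", seed = 18L)
  ds <- hebbsdr:::new_labeled_dataset(V[, 1:3, drop = FALSE],
                                      V[, 4L], "raw")
  fit <- fit_rbm_classifier(ds, n_hidden = 2L, config = cfg)
  expect_lt(tv(fit), tv0)
})

test_that("averaged CD updates vanish when the data comes from the model", {
  # stationarity: enumerate the model marginal and average the CD-1
  # statistics over it with the chain fully sampled; positive and negative
  # expectations coincide
  p <- random_rbm(3L, 2L, seed = 19L, scale = 0.7)
  vs <- enum_binary(3L)
  hs <- enum_binary(2L)
  pv <- enum_visible_marginal(p)
  pos <- matrix(0, 2L, 3L)
  neg <- matrix(0, 2L, 3L)
  for (a in seq_len(nrow(vs))) {
    v <- vs[a, ]
    hp <- hidden_conditional(p, v)
    pos <- pos + pv[a] * hp %*% t(v)
    # expectation over h ~ p(h|v), v1 ~ p(v1|h), h1 ~ p(h1|v1)
    for (b in seq_len(nrow(hs))) {
      h <- hs[b, ]
      ph <- prod(ifelse(h == 1, hp, 1 - hp))
      vp <- visible_conditional(p, h)
      for (c_ in seq_len(nrow(vs))) {
        v1 <- vs[c_, ]
        pv1 <- prod(ifelse(v1 == 1, vp, 1 - vp))
        neg <- neg + pv[a] * ph * pv1 *
          hidden_conditional(p, v1) %*% t(v1)
      }
    }
  }
  expect_equal(pos, neg, tolerance = 1e-10)
})

test_that("free energy agrees with hidden-layer marginalization", {
  p0 <- rbm_params(3L, 4L, seed = 20L)
  p0$W[] <- 0
  expect_equal(free_energy(p0, c(1, 0, 1)), -4 * log(2))

  p <- random_rbm(2L, 2L, seed = 21L)
  for (a in seq_len(4L)) {
    v <- enum_binary(2L)[a, ]
    hs <- enum_binary(2L)
    z <- sum(apply(hs, 1L, function(h) exp(-energy(p, v, h))))
    expect_equal(exp(-free_energy(p, v)), z, tolerance = 1e-12)
  }

  # shifting the bias of the feature units moves both label completions'
  # free energies equally, so the label posterior is invariant
  pj <- random_rbm(4L, 2L, n_label_units = 1L, seed = 22L)
  pj2 <- pj
  pj2$b[1:3] <- pj$b[1:3] + 2.5
  X <- enum_binary(3L)
  f_shift <- apply(X, 1L, function(x) {
    free_energy(pj2, c(x, 1)) - free_energy(pj, c(x, 1))
  })
  expect_equal(f_shift,
               apply(X, 1L, function(x) {
                 free_energy(pj2, c(x, 0)) - free_energy(pj, c(x, 0))
               }), tolerance = 1e-12)
  expect_equal(predict(pj2, X, mode = "exact", posterior = TRUE),
               predict(pj, X, mode = "exact", posterior = TRUE),
               tolerance = 1e-12)
})

test_that("exact prediction equals the enumeration posterior", {
  p <- random_rbm(4L, 2L, n_label_units = 1L, seed = 22L)
  X <- enum_binary(3L)
  post <- predict(p, X, mode = "exact", posterior = TRUE)
  ref <- apply(X, 1L, function(x) enum_label_posterior(p, x))
  expect_equal(post, ref, tolerance = 1e-10)
  expect_identical(predict(p, X, mode = "exact"), as.integer(ref >= 0.5))
})

test_that("Gibbs prediction converges to the exact posterior", {
  p <- random_rbm(4L, 2L, n_label_units = 1L, seed = 23L, scale = 0.8)
  X <- enum_binary(3L)[c(2L, 5L, 8L), ]
  exact <- predict(p, X, mode = "exact", posterior = TRUE)
  set.seed(24)
  gibbs <- predict(p, X, mode = "gibbs", posterior = TRUE,
                   n_gibbs = 20000L, burn_in = 2000L)
  expect_lt(max(abs(gibbs - exact)), 0.02)
})

test_that("label-symmetric parameters tie-break to class 1", {
  p <- rbm_params(4L, 3L, n_label_units = 1L, seed = 25L)
  p$W[, 4L] <- 0          # label unit disconnected
  p$b[4L] <- 0
  x <- matrix(c(0.3, -0.2, 0.9), 1L)
  expect_equal(predict(p, x, mode = "exact", posterior = TRUE)[1L], 0.5)
  expect_identical(predict(p, x, mode = "exact"), 1L)
  set.seed(26)
  expect_identical(predict(p, x, mode = "gibbs"), 1L)
})

test_that("classifier fitting honours its contract end to end", {
  ds <- tiny_dataset(n = 60L, d = 12L, seed = 27L)

  # zero epochs returns the initialization untouched
  cfg0 <- rbm_train_config(epochs = 0L, seed = 28L)
  init <- fit_rbm_classifier(ds, n_hidden = 5L, config = cfg0)
  ref <- rbm_params(13L, 5L, n_label_units = 1L, seed = 28L)
  expect_identical(init$W, ref$W)

  # deterministic given the seed
  cfg <- rbm_train_config(epochs = 5L, batch_size = 10L, seed = 29L)
  f1 <- fit_rbm_classifier(ds, n_hidden = 5L, config = cfg)
  f2 <- fit_rbm_classifier(ds, n_hidden = 5L, config = cfg)
  expect_identical(f1$W, f2$W)

  # compiled fit equals an R-level pcd_update loop on the same stream
  cfgp <- rbm_train_config(epochs = 3L, batch_size = 10L,
                           algorithm = "PCD", seed = 30L)
  fit <- fit_rbm_classifier(ds, n_hidden = 4L, config = cfgp)
  V <- cbind(ds$features, as.numeric(ds$labels))
  p <- rbm_params(ncol(V), 4L, n_label_units = 1L, seed = 30L)
  set.seed(hebbsdr:::derive_seed(30L, 7L))
  chains <- NULL
  for (e in 1:3) {
    perm <- sample.int(nrow(V))
    for (s in seq(1L, nrow(V), 10L)) {
      b <- V[perm[s:(s + 9L)], , drop = FALSE]
      if (is.null(chains)) chains <- list(v = b)
      r <- pcd_update(p, b, chains, cfgp)
      p <- r$params
      chains <- r$chains
    }
  }
  expect_equal(fit$W, p$W, tolerance = 1e-12)
  expect_equal(fit$b, p$b, tolerance = 1e-12)

  # a separable fixed-point problem is learned to 100% train accuracy
  dsep <- tiny_dataset(n = 40L, d = 10L, cov_scale = 1e-12, seed = 31L)
  cfgs <- rbm_train_config(epochs = 30L, batch_size = 10L, seed = 32L)
  fsep <- fit_rbm_classifier(dsep, n_hidden = 8L, config = cfgs)
  set.seed(33)
  pred <- predict(fsep, dsep$features)
  expect_equal(accuracy(pred, dsep$labels), 100)

  expect_error(fit_rbm_classifier(ds, n_hidden = 0L), "positive")
})

test_that("parameters round-trip through the serialization container", {
  p <- random_rbm(4L, 3L, n_label_units = 1L, seed = 34L)
  path <- tempfile(fileext = ".rds")
  save_params(p, path, config = rbm_train_config())
  back <- load_params(path)
  expect_identical(back, p)
  unlink(path)
})
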