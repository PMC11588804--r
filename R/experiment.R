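#' Classification accuracy in percent
#'
#' @param predicted,actual equal-length binary label vectors.
#' @return 100 * (matches / total).
#' @export
accuracy <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(actual) == 0L) stop("empty label vectors", call. = FALSE)
  100 * mean(predicted == actual)
}

#' Configuration of one repeated-run experiment
#'
#' Bundles everything the pipeline needs: the dataset recipe, which models
#' to fit, their training configurations, the shared hidden width, and the
#' repetition protocol (each repetition r reruns the full pipeline with
#' seeds derived from `base_seed + r`).
#'
#' @param dataset a [dataset_spec()].
#' @param models character subset of `c("LR", "MLP", "RBM")`.
#' @param rbm_config an [rbm_train_config()].
#' @param net_config a [net_train_config()] shared by LR and MLP.
#' @param n_hidden hidden width shared by MLP and RBM (default 500).
#' @param repetitions number of pipeline repetitions (default 10).
#' @param base_seed integer seed anchoring the repetition ladder.
#' @param rbm_predict_mode `"gibbs"` (the pipeline's sampling evaluation)
#'   or `"exact"` (closed-form free-energy posterior).
#' @param n_gibbs,burn_in Gibbs-prediction sweep counts.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = dataset_spec(),
                            models = c("LR", "MLP", "RBM"),
                            rbm_config = rbm_train_config(),
                            net_config = net_train_config(),
                            n_hidden = 500L,
                            repetitions = 10L,
                            base_seed = 1L,
                            rbm_predict_mode = c("gibbs", "exact"),
                            n_gibbs = 100L, burn_in = 50L) {
  stopifnot(inherits(dataset, "dataset_spec"))
  models <- match.arg(models, several.ok = TRUE)
  if (repetitions < 1L) stop("`repetitions` must be at least 1",
                             call. = FALSE)
  if (n_hidden < 1L) stop("`n_hidden` must be positive", call. = FALSE)
  structure(list(dataset = dataset, models = models,
                 rbm_config = rbm_config, net_config = net_config,
                 n_hidden = as.integer(n_hidden),
                 repetitions = as.integer(repetitions),
                 base_seed = as.integer(base_seed),
                 rbm_predict_mode = match.arg(rbm_predict_mode),
                 n_gibbs = as.integer(n_gibbs),
                 burn_in = as.integer(burn_in)),
            class = "pipeline_config")
}

model_seed_slot <- c(LR = 11L, MLP = 12L, RBM = 13L)

# Fit and evaluate one model on one train/test split. Each model consumes
# its own derived random sub-stream, so adding or removing a model leaves
# the others' results untouched.
fit_eval_model <- function(model, split, config, rep_seed) {
  seed <- derive_seed(rep_seed, model_seed_slot[[model]])
  if (model == "RBM") {
    cfg <- config$rbm_config
    cfg$seed <- seed
    fit <- fit_rbm_classifier(split$train, n_hidden = config$n_hidden,
                              config = cfg)
    set.seed(derive_seed(rep_seed, 21L))
    pred_train <- predict(fit, split$train$features,
                          mode = config$rbm_predict_mode,
                          n_gibbs = config$n_gibbs, burn_in = config$burn_in)
    pred_test <- predict(fit, split$test$features,
                         mode = config$rbm_predict_mode,
                         n_gibbs = config$n_gibbs, burn_in = config$burn_in)
  } else {
    cfg <- config$net_config
    cfg$seed <- seed
    n_hidden <- if (model == "MLP") config$n_hidden else 0L
    fit <- fit_backprop_net(split$train, n_hidden = n_hidden, config = cfg)
    pred_train <- predict(fit, split$train$features)
    pred_test <- predict(fit, split$test$features)
  }
  c(train = accuracy(pred_train, split$train$labels),
    test = accuracy(pred_test, split$test$labels))
}

# generate -> center -> sparsify -> split for repetition seed `rep_seed`
prepare_split <- function(dataset, rep_seed) {
  spec <- dataset
  spec$seed <- derive_seed(rep_seed, 1L)
  ds <- center_features(generate_gaussian_dataset(spec))
  if (spec$sparsity > 0) {
    ds <- sparsify(ds, spec$sparsity, derive_seed(rep_seed, 2L))
  }
  train_test_split(ds, spec$train_fraction, derive_seed(rep_seed, 3L))
}

#' Run the repeated experiment pipeline
#'
#' For each repetition r = 1..repetitions: generate the two-Gaussian
#' dataset, centre it, sparsify it (if `sparsity > 0`), split 80/20, then
#' fit and evaluate every requested model; all randomness derives from
#' `base_seed + r`. Accuracies are recorded in percent to two decimals and
#' aggregated into means and standard deviations per model.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-stage progress and timing.
#' @return an object of class `experiment_result` with elements `raw`
#'   (data.frame: model, d, sparsity, repetition, train_acc, test_acc),
#'   `summary` (per-model means/sds) and `config`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  rows <- vector("list", config$repetitions * length(config$models))
  k <- 0L
  for (r in seq_len(config$repetitions)) {
    rep_seed <- config$base_seed + r
    t0 <- proc.time()[["elapsed"]]
    split <- prepare_split(config$dataset, rep_seed)
    if (verbose) {
      message(sprintf("[rep %d] generated %d x %d (s = %g) in %.1fs",
                      r, config$dataset$n_samples, config$dataset$n_features,
                      config$dataset$sparsity,
                      proc.time()[["elapsed"]] - t0))
    }
    for (model in config$models) {
      t1 <- proc.time()[["elapsed"]]
      acc <- tryCatch(
        fit_eval_model(model, split, config, rep_seed),
        error = function(e) {
          stop(sprintf("repetition %d, model %s failed: %s",
                       r, model, conditionMessage(e)), call. = FALSE)
        })
      k <- k + 1L
      rows[[k]] <- data.frame(model = model,
                              d = config$dataset$n_features,
                              sparsity = config$dataset$sparsity,
                              repetition = r,
                              train_acc = round(acc[["train"]], 2),
                              test_acc = round(acc[["test"]], 2))
      if (verbose) {
        message(sprintf("[rep %d] %s train %.2f / test %.2f (%.1fs)",
                        r, model, acc[["train"]], acc[["test"]],
                        proc.time()[["elapsed"]] - t1))
      }
    }
  }
  raw <- do.call(rbind, rows)
  new_experiment_result(raw, config)
}

new_experiment_result <- function(raw, config) {
  agg <- lapply(split(raw, raw$model), function(g) {
    data.frame(model = g$model[1L], d = g$d[1L], sparsity = g$sparsity[1L],
               train_mean = mean(g$train_acc), train_sd = stats::sd(g$train_acc),
               test_mean = mean(g$test_acc), test_sd = stats::sd(g$test_acc))
  })
  summary <- do.call(rbind, agg)
  summary <- summary[order(match(summary$model, c("LR", "MLP", "RBM"))), ]
  rownames(summary) <- NULL
  structure(list(raw = raw, summary = summary, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: d = %d, sparsity = %g, %d repetition(s)\n",
              x$config$dataset$n_features, x$config$dataset$sparsity,
              x$config$repetitions))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-4s train %6.2f%% (sd %5.2f)   test %6.2f%% (sd %5.2f)\n",
                s$model[i], s$train_mean[i],
                ifelse(is.na(s$train_sd[i]), 0, s$train_sd[i]),
                s$test_mean[i],
                ifelse(is.na(s$test_sd[i]), 0, s$test_sd[i])))
  }
  invisible(x)
}

#' Run the pipeline across a ladder of sparsities
#'
#' One [run_pipeline()] per sparsity value, everything else held fixed.
#'
#' @param config a [pipeline_config()]; its dataset sparsity is overridden.
#' @param sparsities numeric vector in \[0, 1), e.g. the default ladder
#'   `c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95)`.
#' @return named list of `experiment_result`, in the order given.
#' @export
sparsity_sweep <- function(config,
                           sparsities = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95)) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(sparsities) == 0L) stop("`sparsities` must be non-empty",
                                     call. = FALSE)
  if (any(sparsities < 0 | sparsities >= 1)) {
    stop("sparsities must lie in [0, 1)", call. = FALSE)
  }
  out <- lapply(sparsities, function(s) {
    cfg <- config
    cfg$dataset$sparsity <- s
    run_pipeline(cfg)
  })
  names(out) <- as.character(sparsities)
  out
}

#' Dimensionality-by-sparsity grid of experiments
#'
#' Runs the full pipeline on the Cartesian product of dimensionalities and
#' sparsities and reports the RBM minus LR train- and test-accuracy
#' difference surfaces.
#'
#' @param config a [pipeline_config()] including both `"LR"` and `"RBM"`.
#' @param dims dimensionalities (default `c(1000, 2000, 3000, 4000, 5000)`).
#' @param sparsities sparsity fractions (default as in [sparsity_sweep()]).
#' @return list with `results` (list of lists of `experiment_result`,
#'   indexed `[[dim]][[sparsity]]`), and matrices `test_diff` and
#'   `train_diff` (rows = dims, columns = sparsities, RBM mean minus LR
#'   mean in percentage points).
#' @export
dim_sparsity_grid <- function(config,
                              dims = c(1000L, 2000L, 3000L, 4000L, 5000L),
                              sparsities = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95)) {
  stopifnot(inherits(config, "pipeline_config"))
  if (length(dims) == 0L || length(sparsities) == 0L) {
    stop("grid axes must be non-empty", call. = FALSE)
  }
  if (!all(c("LR", "RBM") %in% config$models)) {
    stop("the grid compares RBM and LR; both must be in `models`",
         call. = FALSE)
  }
  results <- lapply(dims, function(d) {
    cfg <- config
    cfg$dataset$n_features <- as.integer(d)
    cfg$dataset$mean0 <- rep_len(cfg$dataset$mean0, d)
    cfg$dataset$mean1 <- rep_len(cfg$dataset$mean1, d)
    sparsity_sweep(cfg, sparsities)
  })
  names(results) <- as.character(dims)
  pull_diff <- function(col) {
    m <- vapply(results, function(row) {
      vapply(row, function(res) {
        s <- res$summary
        s[[col]][s$model == "RBM"] - s[[col]][s$model == "LR"]
      }, numeric(1L))
    }, numeric(length(sparsities)))
    m <- t(m)
    dimnames(m) <- list(dim = as.character(dims),
                        sparsity = as.character(sparsities))
    m
  }
  list(results = results,
       test_diff = pull_diff("test_mean"),
       train_diff = pull_diff("train_mean"))
}

#' Write experiment results to a tidy CSV report
#'
#' Emits one long-format CSV with a row per (model, setting, repetition)
#' plus `mean` and `sd` aggregate rows, exactly recomputable from the raw
#' rows. Values round-trip losslessly through `data.table::fread`.
#'
#' @param results an `experiment_result` or a (possibly named) list of them.
#' @param path output CSV file.
#' @return the tidy data.frame, invisibly.
#' @export
report <- function(results, path = NULL) {
  if (inherits(results, "experiment_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to report", call. = FALSE)
  tidy <- do.call(rbind, lapply(results, function(res) {
    raw <- res$raw
    raw$stat <- "rep"
    s <- res$summary
    agg <- rbind(
      data.frame(model = s$model, d = s$d, sparsity = s$sparsity,
                 repetition = NA_integer_, train_acc = s$train_mean,
                 test_acc = s$test_mean, stat = "mean"),
      data.frame(model = s$model, d = s$d, sparsity = s$sparsity,
                 repetition = NA_integer_, train_acc = s$train_sd,
                 test_acc = s$test_sd, stat = "sd"))
    rbind(raw, agg)
  }))
  rownames(tidy) <- NULL
  if (!is.null(path)) {
    out <- tidy
    # 17 significant digits so aggregate means/sds round-trip exactly
    out$train_acc <- sprintf("%.17g", out$train_acc)
    out$test_acc <- sprintf("%.17g", out$test_acc)
    data.table::fwrite(out, path, quote = FALSE)
  }
  invisible(tidy)
}

#' Calibrate the covariance scale against the dense baseline
#'
#' The generative model's "small number" (the factor multiplying the
#' inter-mean norm to give the per-feature variance) controls problem
#' difficulty. This routine anchors it to the dense 500-feature
#' logistic-regression benchmark: each candidate scale is run through the
#' LR-only pipeline and the scale whose mean test accuracy is closest to
#' `target` is returned (99.25% reproduces the dense baseline).
#'
#' @param candidates covariance scales to try.
#' @param target mean LR test accuracy (%) to aim for.
#' @param n_features,n_samples dense problem size.
#' @param repetitions pipeline repetitions per candidate.
#' @param base_seed repetition seed anchor.
#' @param net_config LR training configuration.
#' @return list with `cov_scale` (the selected value) and `table`
#'   (candidate, train_mean, test_mean).
#' @export
calibrate_cov_scale <- function(candidates = c(1, 2, 4, 8),
                                target = 99.25,
                                n_features = 500L, n_samples = 2000L,
                                repetitions = 3L, base_seed = 1L,
                                net_config = net_train_config()) {
  rows <- lapply(candidates, function(eps) {
    cfg <- pipeline_config(
      dataset = dataset_spec(n_samples = n_samples, n_features = n_features,
                             cov_scale = eps, sparsity = 0),
      models = "LR", net_config = net_config,
      repetitions = repetitions, base_seed = base_seed)
    s <- run_pipeline(cfg)$summary
    data.frame(cov_scale = eps, train_mean = s$train_mean,
               test_mean = s$test_mean)
  })
  table <- do.call(rbind, rows)
  best <- table$cov_scale[which.min(abs(table$test_mean - target))]
  list(cov_scale = best, table = table)
}
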