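#' Specification of a synthetic two-Gaussian sparse classification problem
#'
#' Describes the generative model used throughout the study: two classes of
#' equal size, class 0 drawn from a multivariate normal centred at `mean0`
#' (default the origin) and class 1 centred at `mean1` (default a vector of
#' fives), both with an isotropic diagonal covariance whose diagonal equals
#' `cov_scale` times the Euclidean norm of `mean1 - mean0`. Samples are then
#' centred feature-wise and, optionally, sparsified by keeping a random
#' subset of features per sample and zeroing the rest.
#'
#' @param n_samples total number of samples (default 2000); the first half
#'   is class 0, the rest class 1.
#' @param n_features dimensionality d (500 for the dense problem, 5000 for
#'   the sparse one).
#' @param mean0,mean1 class mean vectors, recycled to length `n_features`.
#'   They must differ in at least one coordinate.
#' @param cov_scale positive scale factor applied to the inter-mean norm to
#'   give the common per-feature variance (default 4, chosen by
#'   [calibrate_cov_scale()] against the dense logistic-regression problem).
#' @param sparsity fraction s in \[0, 1) of features zeroed per sample;
#'   each sample keeps `round((1 - s) * n_features)` features.
#' @param train_fraction fraction of samples assigned to the training set.
#' @param seed integer seed making the generated dataset reproducible.
#'
#' @return an object of class `dataset_spec`.
#' @export
#' @examples
#' spec <- dataset_spec(n_samples = 200, n_features = 50, sparsity = 0.9)
#' ds <- generate_gaussian_dataset(spec)
#' dim(ds$features)
dataset_spec <- function(n_samples = 2000L,
                         n_features = 5000L,
                         mean0 = 0,
                         mean1 = 5,
                         cov_scale = 4,
                         sparsity = 0.95,
                         train_fraction = 0.8,
                         seed = 1L) {
  stopifnot_scalar_number(n_samples, "n_samples")
  stopifnot_scalar_number(n_features, "n_features")
  stopifnot_scalar_number(cov_scale, "cov_scale")
  stopifnot_scalar_number(sparsity, "sparsity")
  stopifnot_scalar_number(train_fraction, "train_fraction")
  n_samples <- as.integer(n_samples)
  n_features <- as.integer(n_features)
  if (n_samples < 2L) stop("`n_samples` must be at least 2", call. = FALSE)
  if (n_features < 1L) stop("`n_features` must be positive", call. = FALSE)
  if (cov_scale <= 0) stop("`cov_scale` must be positive", call. = FALSE)
  if (sparsity < 0 || sparsity >= 1) {
    stop("`sparsity` must lie in [0, 1)", call. = FALSE)
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  mean0 <- rep_len(as.numeric(mean0), n_features)
  mean1 <- rep_len(as.numeric(mean1), n_features)
  if (all(mean0 == mean1)) {
    stop("`mean0` and `mean1` must differ: class separation is zero",
         call. = FALSE)
  }
  if (round((1 - sparsity) * n_features) < 1) {
    stop("sparsity leaves no feature kept per sample", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_features = n_features,
         mean0 = mean0, mean1 = mean1, cov_scale = cov_scale,
         sparsity = sparsity, train_fraction = train_fraction,
         seed = as.integer(seed)),
    class = "dataset_spec"
  )
}

#' @export
print.dataset_spec <- function(x, ...) {
  cat(sprintf(
    "dataset_spec: n = %d, d = %d, cov_scale = %g, sparsity = %g, train = %g, seed = %d\n",
    x$n_samples, x$n_features, x$cov_scale, x$sparsity, x$train_fraction,
    x$seed))
  invisible(x)
}

new_labeled_dataset <- function(features, labels, stage) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  structure(list(features = features,
                 labels = as.integer(labels),
                 stage = match.arg(stage, c("raw", "centered", "sparsified"))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d samples x %d features, stage = %s\n",
              nrow(x$features), ncol(x$features), x$stage))
  cat(sprintf("  class balance: %d / %d\n",
              sum(x$labels == 0L), sum(x$labels == 1L)))
  invisible(x)
}

#' Draw the raw two-Gaussian dataset
#'
#' Class c rows are i.i.d. N(mean_c, sigma^2 I) with
#' sigma^2 = cov_scale * ||mean1 - mean0||. The first floor(n/2) samples
#' carry label 0 and the remainder label 1.
#'
#' @param spec a [dataset_spec()].
#' @return a `labeled_dataset` at stage `"raw"`.
#' @export
generate_gaussian_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$n_samples
  d <- spec$n_features
  sd <- sqrt(spec$cov_scale * sqrt(sum((spec$mean1 - spec$mean0)^2)))
  n0 <- n %/% 2L
  labels <- c(rep(0L, n0), rep(1L, n - n0))
  set.seed(spec$seed)
  noise <- matrix(stats::rnorm(n * d, sd = sd), nrow = n, ncol = d)
  means <- rbind(matrix(spec$mean0, n0, d, byrow = TRUE),
                 matrix(spec$mean1, n - n0, d, byrow = TRUE))
  new_labeled_dataset(noise + means, labels, "raw")
}

#' Centre every feature at zero
#'
#' Subtracts each column's mean from that column, over the full dataset
#' (before any train/test split). Labels are untouched.
#'
#' @param data a `labeled_dataset` at stage `"raw"`.
#' @return the dataset at stage `"centered"`, every column mean below 1e-9
#'   in absolute value.
#' @export
center_features <- function(data) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (nrow(data$features) == 0L) stop("empty dataset", call. = FALSE)
  if (data$stage != "raw") {
    stop(sprintf("expected a raw dataset, got stage '%s'", data$stage),
         call. = FALSE)
  }
  centered <- sweep(data$features, 2L, colMeans(data$features))
  new_labeled_dataset(centered, data$labels, "centered")
}

#' Zero a random subset of features in every sample
#'
#' For each sample independently, a uniformly random subset of
#' k = round((1 - s) * d) feature indices (drawn without replacement) keeps
#' its values; every other entry becomes exactly 0.
#'
#' @param data a `labeled_dataset` at stage `"centered"`.
#' @param s sparsity fraction in \[0, 1); s = 0 returns the data unchanged
#'   apart from the stage marker.
#' @param seed integer seed for the per-row subset draws.
#' @return the dataset at stage `"sparsified"`; every row has exactly k
#'   nonzero entries (the Gaussian draws are nonzero almost surely).
#' @export
sparsify <- function(data, s, seed) {
  stopifnot(inherits(data, "labeled_dataset"))
  stopifnot_scalar_number(s, "s")
  if (s < 0 || s >= 1) stop("`s` must lie in [0, 1)", call. = FALSE)
  if (data$stage != "centered") {
    stop(sprintf("expected a centered dataset, got stage '%s'", data$stage),
         call. = FALSE)
  }
  x <- data$features
  d <- ncol(x)
  k <- as.integer(round((1 - s) * d))
  if (k < 1L) stop("sparsity leaves no feature kept per sample", call. = FALSE)
  if (k < d) {
    set.seed(seed)
    out <- matrix(0, nrow(x), d)
    for (i in seq_len(nrow(x))) {
      keep <- sample.int(d, k)
      out[i, keep] <- x[i, keep]
    }
    x <- out
  }
  new_labeled_dataset(x, data$labels, "sparsified")
}

#' Random train/test split
#'
#' Permutes the samples and assigns the first round(n * f) to the training
#' set, the remainder to the test set. The two parts are disjoint and their
#' union is the input.
#'
#' @param data a `labeled_dataset` (any stage).
#' @param train_fraction f in (0, 1).
#' @param seed integer seed for the permutation.
#' @return list with elements `train` and `test`, both `labeled_dataset`s at
#'   the input's stage.
#' @export
train_test_split <- function(data, train_fraction, seed) {
  stopifnot(inherits(data, "labeled_dataset"))
  stopifnot_scalar_number(train_fraction, "train_fraction")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(data$features)
  n_train <- as.integer(round(n * train_fraction))
  if (n_train < 1L || n_train >= n) {
    stop("split would leave an empty train or test part", call. = FALSE)
  }
  set.seed(seed)
  perm <- sample.int(n)
  idx_train <- perm[seq_len(n_train)]
  idx_test <- perm[(n_train + 1L):n]
  list(
    train = new_labeled_dataset(data$features[idx_train, , drop = FALSE],
                                data$labels[idx_train], data$stage),
    test = new_labeled_dataset(data$features[idx_test, , drop = FALSE],
                               data$labels[idx_test], data$stage)
  )
}

#' Flip every bit of a binary table
#'
#' @param x matrix (or vector) with entries in \{0, 1\}.
#' @return the same shape with every entry x replaced by 1 - x.
#' @export
flip_bits <- function(x) {
  if (!is_binary(x)) stop("input must be binary (entries in {0, 1})",
                          call. = FALSE)
  1 - x
}

#' Threshold a real-valued table to binary
#'
#' @param x numeric matrix or vector.
#' @param threshold entries strictly above it map to 1, all others to 0
#'   (default 0.5, for intensities scaled to \[0, 1\]).
#' @return binary object of the same shape.
#' @export
binarize <- function(x, threshold = 0.5) {
  stopifnot_scalar_number(threshold, "threshold")
  (x > threshold) * 1
}

# persistence ----------------------------------------------------------------

#' Write / read a labelled dataset
#'
#' `write_dataset` persists the feature matrix with the label as the final
#' column. `format = "tsv"` writes a tab-delimited text matrix with
#' full-precision (round-trippable) doubles; `format = "rds"` writes a
#' compact binary container. `read_dataset` restores either, including the
#' processing stage, losslessly.
#'
#' @param data a `labeled_dataset`.
#' @param path file to write / read.
#' @param format `"tsv"` or `"rds"`; `read_dataset` infers it from the file
#'   extension when not given.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the `labeled_dataset`.
#' @export
write_dataset <- function(data, path, format = c("tsv", "rds")) {
  stopifnot(inherits(data, "labeled_dataset"))
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(list(container = "hebbsdr_labeled_dataset", version = 1L,
                 n = nrow(data$features), d = ncol(data$features),
                 features = data$features, labels = data$labels,
                 stage = data$stage),
            path)
  } else {
    # 17 significant digits so every double round-trips exactly
    chr <- matrix(sprintf("%.17g", data$features), nrow(data$features))
    dt <- data.table::as.data.table(chr)
    data.table::setnames(dt, paste0("f", seq_len(ncol(data$features))))
    dt[, label := data$labels]
    # leading comment line carries the stage so the text form round-trips
    writeLines(sprintf("# hebbsdr labeled_dataset stage=%s", data$stage), path)
    data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path, format = c("auto", "tsv", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "tsv"
  }
  if (format == "rds") {
    obj <- readRDS(path)
    stopifnot(identical(obj$container, "hebbsdr_labeled_dataset"))
    return(new_labeled_dataset(obj$features, obj$labels, obj$stage))
  }
  header <- readLines(path, n = 1L)
  stage <- sub("^# hebbsdr labeled_dataset stage=", "", header)
  dt <- data.table::fread(path, sep = "\t", skip = 1L, header = TRUE)
  labels <- as.integer(dt$label)
  dt[, label := NULL]
  feats <- as.matrix(dt)
  storage.mode(feats) <- "double"
  new_labeled_dataset(feats, labels, stage)
}

#' Read an IDX-format binary image/label file
#'
#' Minimal reader for the IDX container used by classic image benchmarks:
#' a 4-byte magic number (third byte = element type, fourth = number of
#' dimensions), big-endian 32-bit dimension sizes, then the row-major
#' payload. Only unsigned-byte payloads (type 0x08) are supported, which
#' covers the standard image and label files. Images come back as an
#' n x (rows*cols) double matrix scaled to \[0, 1\]; label files as an
#' integer vector.
#'
#' @param path an IDX file (uncompressed).
#' @return matrix (images) or integer vector (labels).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (magic[1] != 0L || magic[2] != 0L) stop("not an IDX file", call. = FALSE)
  if (magic[3] != 0x08) stop("only unsigned-byte IDX payloads supported",
                             call. = FALSE)
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  payload <- readBin(con, "integer", n = prod(dims), size = 1L,
                     signed = FALSE)
  if (ndim == 1L) return(as.integer(payload))
  m <- matrix(as.numeric(payload) / 255, nrow = dims[1],
              ncol = prod(dims[-1]), byrow = TRUE)
  m
}
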