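# Shared 3-layer backpropagation MLP engine: configuration, stratified
# splitting, feature scaling, training with early stopping, prediction.

#' ANN training configuration
#'
#' Architecture and optimizer settings shared by the screening tier and the
#' leave-one-gene-out inference tier.  The network is a 3-layer sigmoid
#' perceptron (inputs, `n_hidden` hidden nodes, one output) trained by
#' online backpropagation with momentum.  After every epoch the test-set MSE
#' is evaluated; training stops at `max_train_epochs`, or once the best test
#' MSE has failed to improve by at least `min_mse_improvement` over a
#' sliding window of `test_window_epochs` epochs.  The retained model is
#' always the best-test-MSE snapshot.
#'
#' @param n_hidden hidden nodes (default 2 — the 1-2-1 screening
#'   architecture uses one input, two hidden, one output).
#' @param max_train_epochs training epoch budget (default 300).
#' @param test_window_epochs early-stopping patience window (default 100).
#' @param min_mse_improvement minimum test-MSE improvement counted as
#'   progress (default 0.01).
#' @param learning_rate online gradient step (default 0.1).
#' @param momentum momentum coefficient (default 0.5).
#' @param weight_init_halfwidth weights initialized uniformly in
#'   `[-h, h]` (default 0.5).
#' @param seed integer master seed.
#' @return an `ann_config` list.
#' @export
ann_config <- function(n_hidden = 2L, max_train_epochs = 300L,
                       test_window_epochs = 100L, min_mse_improvement = 0.01,
                       learning_rate = 0.1, momentum = 0.5,
                       weight_init_halfwidth = 0.5, seed = 1L) {
  stopifnot(n_hidden >= 1, max_train_epochs >= 1, test_window_epochs >= 1,
            min_mse_improvement >= 0, learning_rate > 0, momentum >= 0,
            weight_init_halfwidth > 0, is.finite(learning_rate),
            is.finite(momentum))
  structure(list(n_hidden = as.integer(n_hidden),
                 max_train_epochs = as.integer(max_train_epochs),
                 test_window_epochs = as.integer(test_window_epochs),
                 min_mse_improvement = min_mse_improvement,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_init_halfwidth = weight_init_halfwidth,
                 seed = as.numeric(seed)),
            class = "ann_config")
}

#' Read / write an ANN configuration as YAML
#' @param path YAML file path.
#' @return for the reader, an [ann_config()]; for the writer, the path.
#' @export
read_ann_config <- function(path) {
  do.call(ann_config, yaml::read_yaml(path))
}

#' @param config an [ann_config()].
#' @rdname read_ann_config
#' @export
write_ann_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Train/test/validation split ratio
#'
#' @param train,test,validation partition fractions; each in (0,1), summing
#'   to 1.  Default 0.6 / 0.2 / 0.2 (60% of samples train, 20% drive early
#'   stopping, 20% measure classification performance).
#' @return a `split_ratio` list.
#' @export
split_ratio <- function(train = 0.6, test = 0.2, validation = 0.2) {
  r <- c(train = train, test = test, validation = validation)
  if (any(r <= 0) || any(r >= 1)) .stopf("each split fraction must lie in (0, 1)")
  if (abs(sum(r) - 1) > 1e-12) .stopf("split fractions must sum to 1")
  structure(as.list(r), class = "split_ratio")
}

# largest-remainder apportionment of n into the three partitions,
# guaranteeing one sample per partition when n >= 3
.apportion <- function(n, ratio) {
  target <- n * c(ratio$train, ratio$test, ratio$validation)
  base <- floor(target)
  rem <- target - base
  left <- n - sum(base)
  if (left > 0) {
    # ties broken in train > test > validation order (stable sort)
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  if (n >= 3 && any(base == 0)) {
    for (k in which(base == 0)) {
      donor <- which.max(base)
      base[donor] <- base[donor] - 1
      base[k] <- base[k] + 1
    }
  }
  base
}

#' Randomly partition samples into train / test / validation sets
#'
#' Stratified by class label: within each class, samples are shuffled
#' deterministically (given `seed`) and apportioned by largest-remainder
#' rounding of the ratio, with at least one sample per partition per class.
#'
#' @param labels class label per sample (factor/character/numeric), or NULL
#'   for an unstratified split (regression tasks).
#' @param ratio a [split_ratio()].
#' @param seed integer seed; identical seeds give identical partitions.
#' @param n number of samples when `labels` is NULL.
#' @return list of integer index vectors `train`, `test`, `validation`;
#'   disjoint, jointly covering all samples.
#' @export
split_samples <- function(labels, ratio = split_ratio(), seed = 1L, n = NULL) {
  if (is.null(labels)) {
    if (is.null(n)) .stopf("`n` is required when labels are NULL")
    labels <- rep("all", n)
  }
  labels <- as.character(labels)
  n <- length(labels)
  out <- list(train = integer(0), test = integer(0), validation = integer(0))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 3)
      .stopf(paste0("class '%s' has %d sample(s); at least 3 per class are ",
                    "needed to place one in each partition"), cl, length(idx))
    idx <- .lehmer_shuffle(idx, .child_seed(seed, cl))
    sizes <- .apportion(length(idx), ratio)
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    out$test <- c(out$test, idx[sizes[1] + seq_len(sizes[2])])
    out$validation <- c(out$validation, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  lapply(out, sort)
}

#' Sigmoid activation
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Mean squared error
#' @param predicted,observed equal-length numeric vectors.
#' @return mean of squared differences.
#' @export
mse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    .stopf("length mismatch: %d vs %d", length(predicted), length(observed))
  if (!length(predicted)) .stopf("mse of empty vectors is undefined")
  mean((predicted - observed)^2)
}

#' Min-max feature scaling fitted on the training partition
#'
#' Scaling parameters (per-feature min and max) are fitted on the training
#' rows only and applied to all rows; values outside the training range are
#' clipped to `[0, 1]`.  A constant training feature maps everywhere to 0.5.
#'
#' @param train numeric matrix (or vector) of training values.
#' @param apply_to values to scale (defaults to `train`).
#' @return scaled values in `[0, 1]`, same shape as `apply_to`.
#' @export
scale_features <- function(train, apply_to = train) {
  vec_in <- is.null(dim(apply_to))
  train <- as.matrix(train)
  apply_to <- as.matrix(apply_to)
  lo <- apply(train, 2, min)
  hi <- apply(train, 2, max)
  out <- apply_to
  for (j in seq_len(ncol(out))) {
    if (hi[j] - lo[j] <= 0) {
      out[, j] <- 0.5
    } else {
      out[, j] <- pmin(1, pmax(0, (apply_to[, j] - lo[j]) / (hi[j] - lo[j])))
    }
  }
  if (vec_in) out <- drop(out)
  out
}

#' Train a 3-layer MLP with early stopping
#'
#' Online backpropagation with momentum; sample order is reshuffled each
#' epoch from the configured seed.  Training halts at the epoch budget or
#' when the best test-set MSE has not improved by at least
#' `min_mse_improvement` over the last `test_window_epochs` epochs; the
#' returned model is the best-test-MSE snapshot.
#'
#' @param inputs numeric matrix, samples x features, scaled to `[0, 1]`.
#' @param targets numeric vector in `[0, 1]` (class codes or scaled
#'   expression).
#' @param split list with integer `train` and `test` index vectors (1-based)
#'   as from [split_samples()].
#' @param config an [ann_config()]; its `seed` drives initialization and
#'   epoch shuffles.
#' @return an `mlp_train_record`: `model` (class `mlp`, the best snapshot
#'   with `input_weights` ((n_in+1) x n_hidden, bias last row) and
#'   `output_weights` (n_hidden+1, bias last)), `train_mse_by_epoch`,
#'   `test_mse_by_epoch`, `stop_epoch`, `best_test_mse`.
#' @export
mlp_train <- function(inputs, targets, split, config = ann_config()) {
  inputs <- as.matrix(inputs)
  if (nrow(inputs) != length(targets))
    .stopf("inputs (%d rows) and targets (%d) are not aligned",
           nrow(inputs), length(targets))
  fit <- .mlp_train_cpp(inputs, as.numeric(targets),
                        as.integer(split$train) - 1L,
                        as.integer(split$test) - 1L,
                        config$n_hidden, config$max_train_epochs,
                        config$test_window_epochs, config$min_mse_improvement,
                        config$learning_rate, config$momentum,
                        config$weight_init_halfwidth, .seed_norm(config$seed))
  model <- structure(list(input_weights = fit$input_weights,
                          output_weights = fit$output_weights),
                     class = "mlp")
  structure(list(model = model,
                 train_mse_by_epoch = fit$train_mse_by_epoch,
                 test_mse_by_epoch = fit$test_mse_by_epoch,
                 stop_epoch = fit$stop_epoch,
                 best_test_mse = fit$best_test_mse),
            class = "mlp_train_record")
}

#' Forward pass of a trained MLP
#' @param model an `mlp` as returned inside [mlp_train()].
#' @param inputs numeric matrix (samples x features) or vector for a
#'   single-input model.
#' @return predicted values in (0, 1), one per input row.
#' @export
mlp_predict <- function(model, inputs) {
  if (is.null(dim(inputs))) inputs <- matrix(inputs, ncol = nrow(model$input_weights) - 1L)
  .mlp_predict_cpp(model$input_weights, model$output_weights, as.matrix(inputs))
}

#' Export per-epoch training losses as TSV
#' @param record an `mlp_train_record`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_train_record <- function(record, path) {
  df <- data.frame(epoch = seq_along(record$train_mse_by_epoch),
                   train_mse = record$train_mse_by_epoch,
                   test_mse = record$test_mse_by_epoch)
  .write_tsv(df, path)
}

# linearized source->output influence of a trained model:
# sum over hidden nodes of input weight x output weight (biases excluded)
.mlp_influence <- function(model) {
  n_in <- nrow(model$input_weights) - 1L
  n_h <- ncol(model$input_weights)
  as.numeric(model$input_weights[seq_len(n_in), , drop = FALSE] %*%
               model$output_weights[seq_len(n_h)])
}
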