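#' 1-D CNN specification for temporal-coding classification
#'
#' Five strided convolutional layers with ReLU and 0.2 dropout per layer,
#' global average pooling and a dense softmax head, trained with Adam
#' (initial learning rate 0.001, reduce-on-plateau) on categorical
#' cross-entropy with early stopping. Channel counts and kernel sizes are
#' configuration; the defaults keep the trainable parameter count of order
#' 10^4. Strides default to a schedule that shrinks the input length to a
#' few dozen time steps by the last layer, whatever the input length, so
#' the same spec serves full 10 s trains and short segments.
#'
#' @param input_len input length in ms (binary 1 ms bins).
#' @param channels per-layer output channel counts (length 5).
#' @param kernels per-layer kernel sizes.
#' @param strides per-layer strides, or `NULL` to derive from `input_len`.
#' @param dropout dropout probability applied to each conv layer.
#' @param lr initial Adam learning rate.
#' @param lr_factor,lr_patience reduce-on-plateau: multiply `lr` by
#'   `lr_factor` after `lr_patience` epochs without training-loss
#'   improvement.
#' @param batch_size minibatch size (small: datasets hold tens to a few
#'   hundred trials and Adam needs enough update steps).
#' @param max_epochs,patience early stopping: stop after `patience` epochs
#'   without improvement; the best-loss weights are kept.
#' @param input_scale fixed multiplier applied to the 0/1 inputs so that
#'   first-layer pre-activations are of order 1 despite the ~1-3% spike
#'   density (a numerical conditioning choice, not a tunable).
#' @return list of class `cnn_spec`.
#' @export
cnn_spec <- function(input_len = 10000L, channels = c(8L, 16L, 16L, 16L, 16L),
                     kernels = rep(7L, 5L), strides = NULL, dropout = 0.2,
                     lr = 0.001, lr_factor = 0.5, lr_patience = 5L,
                     batch_size = 8L, max_epochs = 80L, patience = 12L,
                     input_scale = 10) {
  input_len <- as.integer(input_len)
  n_layers <- length(channels)
  stopifnot(length(kernels) == n_layers, input_len >= max(kernels))
  if (is.null(strides)) {
    strides <- integer(n_layers)
    len <- input_len
    for (l in seq_len(n_layers)) {
      strides[l] <- if (len > 1000L) 5L else if (len > 120L) 2L else 1L
      k <- min(kernels[l], len)
      len <- (len - k) %/% strides[l] + 1L
    }
  }
  # clamp kernels to what the shrinking length allows
  len <- input_len
  for (l in seq_len(n_layers)) {
    kernels[l] <- min(kernels[l], len)
    len <- (len - kernels[l]) %/% strides[l] + 1L
  }
  structure(list(input_len = input_len, channels = as.integer(channels),
                 kernels = as.integer(kernels), strides = as.integer(strides),
                 dropout = dropout, lr = lr, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 input_scale = input_scale),
            class = "cnn_spec")
}

#' Fit the 1-D CNN on binary spike trains
#'
#' @param X numeric matrix, rows = trials, columns = 1 ms bins (0/1).
#' @param y factor of class labels.
#' @param spec a [cnn_spec()] (defaults derived from `ncol(X)`).
#' @param seed integer seed for weight init, shuffling and dropout.
#' @return list of class `cnn_model` (weights plus the label set).
#' @export
cnn_fit <- function(X, y, spec = NULL, seed = 1L) {
  y <- droplevels(factor(y))
  if (is.null(spec)) spec <- cnn_spec(input_len = ncol(X))
  if (spec$input_len != ncol(X))
    spec <- cnn_spec(input_len = ncol(X), channels = spec$channels,
                     kernels = spec$kernels, dropout = spec$dropout,
                     lr = spec$lr, lr_factor = spec$lr_factor,
                     lr_patience = spec$lr_patience,
                     batch_size = spec$batch_size,
                     max_epochs = spec$max_epochs, patience = spec$patience,
                     input_scale = spec$input_scale)
  fit <- cpp_cnn_train(X * spec$input_scale, as.integer(y) - 1L, nlevels(y),
                       spec$channels, spec$kernels, spec$strides,
                       spec$dropout, spec$lr, spec$batch_size,
                       spec$max_epochs, spec$patience, spec$lr_patience,
                       spec$lr_factor, 1e-5, as.integer(seed %% 2147483647))
  fit$classes <- levels(y)
  fit$spec <- spec
  class(fit) <- "cnn_model"
  fit
}

#' Predict class probabilities / classes with a fitted CNN
#'
#' @param model a `cnn_model`.
#' @param X input matrix (same length as training inputs).
#' @param levels_out factor levels for returned class predictions.
#' @return `cnn_predict_proba`: matrix of class probabilities;
#'   `cnn_predict_class`: factor of argmax classes.
#' @export
cnn_predict_proba <- function(model, X) {
  p <- cpp_cnn_predict(unclass(model), X * model$spec$input_scale)
  colnames(p) <- model$classes
  p
}

#' @rdname cnn_predict_proba
#' @export
cnn_predict_class <- function(model, X, levels_out = model$classes) {
  p <- cnn_predict_proba(model, X)
  factor(model$classes[max.col(p, ties.method = "first")],
         levels = levels_out)
}

#' Temporal-coding expression classification
#'
#' Trains and evaluates the 1-D CNN on full binary spike trains of one
#' afferent subtype under repeated stratified cross-validation.
#'
#' @param dataset a [spike_dataset()] restricted to one subtype (or pass
#'   `subtype`).
#' @param subtype optional subtype filter.
#' @param cv a [cv_spec()].
#' @param spec a [cnn_spec()].
#' @param group_by_unit keep each unit's trials in one fold.
#' @return a `classification_report`.
#' @export
train_eval_cnn <- function(dataset, subtype = NULL, cv = cv_spec(),
                           spec = NULL, group_by_unit = FALSE) {
  if (!is.null(subtype)) dataset <- filter_dataset(dataset, subtype = subtype)
  dataset <- sort_dataset(dataset)
  info <- dataset_info(dataset)
  if (length(unique(info$subtype)) > 1L)
    stop("dataset spans multiple subtypes; pass subtype=")
  X <- binary_matrix(dataset)
  y <- factor(info$expression,
              levels = intersect(EXPRESSIONS, unique(info$expression)))
  run_cv(X, y, cv, classifier = "cnn", cnn = spec,
         groups = if (group_by_unit) info$unit_id else NULL)
}

#' Stack a dataset's binarized trains into a matrix
#'
#' @param dataset a [spike_dataset()].
#' @return numeric matrix, one row per trial (in dataset order), columns =
#'   1 ms bins.
#' @export
binary_matrix <- function(dataset) {
  t(vapply(dataset$trials, binarize, integer(dataset$duration_ms)))
}
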