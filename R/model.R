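#' CNN configuration
#'
#' Describes the compact sequential network used throughout the package:
#' stacked valid-convolution + ReLU + 2x2 max-pool blocks, one dense ReLU
#' layer with dropout, and a single sigmoid output giving the malignancy
#' probability. The default stack (16, 32, 64 filters with 3x3 kernels, dense
#' 64, dropout 0.5, Adam at 1e-3, 50 epochs, batch 32) keeps the parameter
#' count below half a million at the 100x100 input size; every choice is
#' overridable.
#'
#' @param input_size `c(height, width)` of the (single-channel) input.
#' @param conv_filters Integer vector of filter counts, one per block.
#' @param kernel,pool Square kernel and pooling sizes.
#' @param dense_units Units in the dense layer.
#' @param dropout Dropout fraction in `[0, 1)` on the dense layer.
#' @param learning_rate Adam learning rate.
#' @param epochs,batch_size Training schedule.
#' @param seed Integer seed for weight initialization, shuffling and dropout.
#' @return An object of class `cnn_config`.
#' @export
cnn_config <- function(input_size = c(100L, 100L),
                       conv_filters = c(16L, 32L, 64L), kernel = 3L,
                       pool = 2L, dense_units = 64L, dropout = 0.5,
                       learning_rate = 1e-3, epochs = 50L, batch_size = 32L,
                       seed = 1L) {
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (length(input_size) != 2L) stopf("input_size must be c(height, width)")
  structure(list(input_size = as.integer(input_size),
                 conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer shapes and parameter count for a configuration
#'
#' @param config A [cnn_config()].
#' @return A list with `flat` (flattened feature length) and `n_params`.
#' @export
cnn_shape <- function(config) {
  h <- config$input_size[1]; w <- config$input_size[2]; ch <- 1L
  n_params <- 0L
  for (f in config$conv_filters) {
    h <- h - config$kernel + 1L; w <- w - config$kernel + 1L
    if (h < 1L || w < 1L) stopf("network does not fit the input size")
    n_params <- n_params + f * (ch * config$kernel^2 + 1L)
    h <- h %/% config$pool; w <- w %/% config$pool
    if (h < 1L || w < 1L) stopf("pooling collapses the feature map")
    ch <- f
  }
  flat <- h * w * ch
  n_params <- n_params + config$dense_units * (flat + 1L) +
    (config$dense_units + 1L)
  list(flat = flat, n_params = n_params)
}

#' Build an untrained CNN
#'
#' Initializes weights (He-scaled Gaussians, zero biases) deterministically
#' from `config$seed`.
#'
#' @param config A [cnn_config()].
#' @return An object of class `cnn_model` with fields `config`, `weights`,
#'   `n_params` and (after [cnn_train()]) `history`.
#' @export
cnn_build <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  shape <- cnn_shape(config)
  weights <- cnn_init_cpp(config$input_size[1], config$input_size[2],
                          config$conv_filters, config$kernel, config$pool,
                          config$dense_units, config$seed)
  structure(list(config = config, weights = weights,
                 n_params = shape$n_params, history = NULL),
            class = "cnn_model")
}

images_to_cube <- function(images, config) {
  h <- config$input_size[1]; w <- config$input_size[2]
  if (is.array(images) && length(dim(images)) == 3L) {
    arr <- images
  } else {
    arr <- array(0, dim = c(h, w, length(images)))
    for (i in seq_along(images)) {
      m <- images[[i]]
      if (nrow(m) != h || ncol(m) != w)
        stopf("image %d is %dx%d, expected %dx%d", i, nrow(m), ncol(m), h, w)
      arr[, , i] <- m
    }
  }
  if (dim(arr)[1] != h || dim(arr)[2] != w)
    stopf("images are %dx%d, expected %dx%d", dim(arr)[1], dim(arr)[2], h, w)
  arr / 255
}

#' Train the CNN
#'
#' Holds out `round(val_fraction * n)` images (seeded shuffle; R's round
#' halves-to-even rule decides ties) for validation, then runs mini-batch
#' Adam on a class-weighted binary cross-entropy. With the default
#' `class_weights = TRUE` each class is weighted inversely to its frequency
#' in the training partition, so the imbalanced task (roughly 5 non-malignant
#' per malignant) cannot be solved by the degenerate all-negative classifier.
#'
#' @param model A `cnn_model` from [cnn_build()].
#' @param images List of matrices or an `(h, w, n)` array, values 0-255.
#' @param labels 0/1 vector, one per image.
#' @param val_fraction Fraction held out for validation.
#' @param seed Integer seed for the split and for training randomness.
#' @param class_weights Weight classes inversely to frequency?
#' @param epochs Optional override of `config$epochs`.
#' @return The trained `cnn_model`, with a `history` data frame (one row per
#'   epoch: `loss`, `acc`, `val_loss`, `val_acc`).
#' @export
cnn_train <- function(model, images, labels, val_fraction = 0.25, seed = 1L,
                      class_weights = TRUE, epochs = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  x <- images_to_cube(images, cfg)
  n <- dim(x)[3]
  if (length(labels) != n) stopf("labels and images differ in length")
  n_val <- round(val_fraction * n)
  val_idx <- if (n_val > 0)
    withr::with_seed(seed, sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  ytr <- labels[train_idx]
  if (length(unique(ytr)) < 2L)
    stopf("training partition contains a single class")
  if (class_weights) {
    w1 <- length(ytr) / (2 * sum(ytr == 1))
    w0 <- length(ytr) / (2 * sum(ytr == 0))
  } else {
    w0 <- w1 <- 1
  }
  epochs <- if (is.null(epochs)) cfg$epochs else as.integer(epochs)
  xval <- x[, , val_idx, drop = FALSE]
  fit <- cnn_train_cpp(model$weights, x[, , train_idx, drop = FALSE], ytr,
                       xval, labels[val_idx], cfg$conv_filters, cfg$kernel,
                       cfg$pool, cfg$dense_units, epochs, cfg$batch_size,
                       cfg$learning_rate, cfg$dropout, w0, w1, seed)
  model$weights <- fit$weights
  model$history <- data.frame(epoch = seq_len(epochs),
                              loss = fit$history[, 1], acc = fit$history[, 2],
                              val_loss = fit$history[, 3],
                              val_acc = fit$history[, 4])
  model$val_idx <- val_idx
  model
}

#' Predict malignancy probabilities
#'
#' @param model A `cnn_model`.
#' @param images List of matrices or an `(h, w, n)` array, values 0-255.
#' @return Numeric scores in `[0, 1]`, one per image; thresholding at 0.5
#'   gives hard labels.
#' @export
predict_proba <- function(model, images) {
  stopifnot(inherits(model, "cnn_model"))
  cfg <- model$config
  x <- images_to_cube(images, cfg)
  as.numeric(cnn_predict_cpp(model$weights, x, cfg$conv_filters, cfg$kernel,
                             cfg$pool, cfg$dense_units))
}

#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  p <- predict_proba(object, newdata)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("Compact CNN: %s conv filters, dense %d, %s parameters%s\n",
              paste(x$config$conv_filters, collapse = "-"),
              x$config$dense_units, format(x$n_params, big.mark = ","),
              if (is.null(x$history)) " (untrained)" else " (trained)"))
  invisible(x)
}
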