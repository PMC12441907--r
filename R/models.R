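#' Fit the classifier stage of a hybrid model
#'
#' Step 2 of the hybrid architecture: a classical classifier trained on the
#' flattened convolutional activations of a trained CNN encoder.
#'
#' @param features An `encoder_features` matrix from [extract_features()] (a
#'   plain matrix is accepted).
#' @param y 0/1 labels aligned with the feature rows.
#' @param spec A [classifier_spec()].
#' @return A `grn_classifier` (probability contract in `[0, 1]`).
#' @export
fit_hybrid <- function(features, y, spec) {
  fit_classifier(spec, features, y)
}

#' Train a full hybrid model: CNN encoder plus classical classifier
#'
#' Step 1 trains a CNN on the labeled pair feature matrix; step 2 extracts its
#' flattened convolutional activations and fits the requested classifier on
#' them. The returned object predicts directly from raw `2S`-column pair
#' feature matrices.
#'
#' @param X Pair feature matrix (`n x 2S`).
#' @param y 0/1 labels.
#' @param encoder_config A [model_config()] with `model_family = "cnn"`.
#' @param classifier A [classifier_spec()].
#' @param epochs Encoder training epochs (default: config value).
#' @return An object of class `grn_hybrid` with elements `encoder` and
#'   `classifier`.
#' @export
train_hybrid <- function(X, y, encoder_config, classifier,
                         epochs = encoder_config$epochs) {
  if (encoder_config$model_family != "cnn") {
    fail("the hybrid encoder must be a CNN")
  }
  enc <- build_model(encoder_config, ncol(X))
  enc <- train_model(enc, X, y, epochs = epochs)
  feats <- extract_features(enc, X)
  cls <- fit_hybrid(feats, y, classifier)
  structure(list(encoder = enc, classifier = cls), class = "grn_hybrid")
}

#' @export
predict.grn_hybrid <- function(object, newdata, ...) {
  feats <- extract_features(object$encoder, newdata)
  predict(object$classifier, feats)
}

#' @export
print.grn_hybrid <- function(x, ...) {
  cat("Hybrid model\n")
  print(x$encoder)
  print(x$classifier)
  invisible(x)
}

#' Kernel-count grid experiment for the CNN encoder
#'
#' Trains one BCE-loss CNN per `(k1, k2)` combination of first/second-layer
#' filter counts and records its holdout accuracy, reproducing the
#' kernel-number sweep over `{8, 16, 32, 64, 128, 256}` at kernel size 3x3.
#'
#' @param k_values Integer vector of filter counts to sweep.
#' @param train,holdout Lists with elements `x` (feature matrix) and `y`
#'   (0/1 labels).
#' @param config Shared [model_config()] (loss forced to `"bce"`); its seed
#'   is re-derived per grid cell so each cell is independently reproducible.
#' @return A `length(k) x length(k)` accuracy matrix (rows = k1, columns =
#'   k2) with a `seeds` attribute recording the per-cell seeds.
#' @export
kernel_grid_experiment <- function(k_values, train, holdout,
                                   config = model_config("cnn")) {
  k_values <- as.integer(k_values)
  if (!length(k_values)) fail("k_values must be nonempty")
  acc <- matrix(NA_real_, length(k_values), length(k_values),
                dimnames = list(k1 = k_values, k2 = k_values))
  seeds <- acc
  for (i in seq_along(k_values)) {
    for (j in seq_along(k_values)) {
      cell_seed <- derive_seed(config$seed, "kernel_grid", i * 1000L + j)
      cfg <- config
      cfg$loss <- "bce"
      cfg$conv_kernels <- c(k_values[i], k_values[j])
      cfg$seed <- cell_seed
      m <- build_model(cfg, ncol(train$x))
      m <- train_model(m, train$x, train$y)
      p <- predict(m, holdout$x)
      acc[i, j] <- mean((p >= 0.5) == (holdout$y == 1))
      seeds[i, j] <- cell_seed
    }
  }
  attr(acc, "seeds") <- seeds
  acc
}
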