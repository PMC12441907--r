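# Compact neural-network engine: 2 x S convolutional input grids, 3x3 "same"
# convolutions, (1,2) max pooling along the sample axis, dense layers with
# dropout, a sigmoid output, eight selectable losses and an RMSprop optimizer.
# All math is plain matrix algebra; convolution uses precomputed im2col index
# maps so the inner loop is a single BLAS multiply per layer.

.loss_names <- c("bce", "hinge", "mse", "msle", "mae", "poisson", "huber", "logcosh")
.huber_delta <- 1.0
.prob_eps <- 1e-7

#' Reshape a pair feature row to a 2 x S grid and back
#'
#' Row 1 of the grid is the TF expression block, row 2 the target block; the
#' 3x3 convolution kernels therefore mix the two genes locally along the
#' sample axis. `grid_to_pair` is the exact inverse.
#'
#' @param row Numeric vector of even length `2S` (TF block then target block).
#' @return `pair_to_grid`: a `2 x S` numeric matrix.
#' @export
#' @examples
#' pair_to_grid(c(1, 2, 3, 4, 5, 6))
pair_to_grid <- function(row) {
  if (length(row) %% 2 != 0) fail("pair row must have even length, got %d", length(row))
  matrix(row, nrow = 2, byrow = TRUE)
}

#' @rdname pair_to_grid
#' @param grid A `2 x S` matrix.
#' @export
grid_to_pair <- function(grid) {
  if (!is.matrix(grid) || nrow(grid) != 2) fail("grid must be a 2 x S matrix")
  as.vector(t(grid))
}

#' Model configuration for FCN and CNN training
#'
#' Defaults mirror the study configuration: two dense layers of 256 and 128
#' units, dropout after each, RMSprop with learning rate 3e-5, batch size 100,
#' 100 epochs, binary cross-entropy loss. For CNNs, two stacked 3x3
#' convolutions with `conv_kernels` filters each, ReLU activations, and (1,2)
#' max pooling after each convolution.
#'
#' @param model_family `"fcn"` or `"cnn"`.
#' @param loss One of `"bce"`, `"hinge"`, `"mse"`, `"msle"`, `"mae"`,
#'   `"poisson"`, `"huber"`, `"logcosh"`.
#' @param conv_kernels Integer pair `(k1, k2)`: filter counts of the two
#'   convolutional layers (CNN only).
#' @param kernel_size Fixed at `c(3, 3)`.
#' @param dense_units Units of the two dense layers.
#' @param dropout_rate Dropout fraction after each dense layer.
#' @param learning_rate RMSprop learning rate (> 0).
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param optimizer Only `"rmsprop"` is implemented.
#' @param seed Integer seed controlling weight initialization, batch
#'   shuffling, and dropout masks.
#' @return A list of class `model_config`.
#' @export
model_config <- function(model_family = c("cnn", "fcn"), loss = "bce",
                         conv_kernels = c(8L, 8L), kernel_size = c(3L, 3L),
                         dense_units = c(256L, 128L), dropout_rate = 0.2,
                         learning_rate = 3e-5, batch_size = 100L,
                         epochs = 100L, optimizer = "rmsprop", seed = 1L) {
  model_family <- match.arg(model_family)
  if (!loss %in% .loss_names) {
    fail("unknown loss '%s'; valid losses: %s", loss, paste(.loss_names, collapse = ", "))
  }
  if (!identical(as.integer(kernel_size), c(3L, 3L))) fail("kernel_size is fixed at (3, 3)")
  if (learning_rate <= 0) fail("learning_rate must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) fail("dropout_rate must be in [0, 1)")
  if (optimizer != "rmsprop") fail("only the 'rmsprop' optimizer is implemented")
  conv_kernels <- as.integer(conv_kernels)
  if (length(conv_kernels) != 2 || any(conv_kernels < 1)) {
    fail("conv_kernels must be two positive integers")
  }
  structure(list(model_family = model_family, loss = loss,
                 conv_kernels = conv_kernels, kernel_size = c(3L, 3L),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "model_config")
}

# ---- geometry ---------------------------------------------------------------

# im2col index maps for a 3x3 "same" convolution on a 2 x W grid with C input
# channels. Position p = h + 2*(w-1); padded cells point at a shared zero
# column appended to the input.
conv_indices <- function(W, C) {
  H <- 2L
  HW <- H * W
  P <- matrix(NA_integer_, HW, 9L)
  for (dw in -1:1) {
    for (dh in -1:1) {
      k <- (dh + 2L) + 3L * (dw + 1L)
      w <- rep(seq_len(W), each = H)
      h <- rep.int(1:2, W)
      hh <- h + dh
      ww <- w + dw
      ok <- hh >= 1L & hh <= H & ww >= 1L & ww <= W
      P[ok, k] <- hh[ok] + H * (ww[ok] - 1L)
    }
  }
  zero_col <- HW * C + 1L
  colIdx <- integer(HW * 9L * C)
  pos <- 1L
  for (cc in seq_len(C)) {
    for (k in 1:9) {
      v <- P[, k] + HW * (cc - 1L)
      v[is.na(P[, k])] <- zero_col
      colIdx[pos:(pos + HW - 1L)] <- v
      pos <- pos + HW
    }
  }
  list(P = P, colIdx = colIdx, HW = HW)
}

# (1,2) max-pool index pairs along the sample axis for a 2 x W grid, C channels
pool_indices <- function(W, C) {
  W2 <- W %/% 2L
  if (W2 < 1L) fail("grid too narrow to pool (width %d)", W)
  HW <- 2L * W
  HW2 <- 2L * W2
  i1 <- integer(HW2 * C)
  for (cc in seq_len(C)) {
    w2 <- rep(seq_len(W2), each = 2L)
    h <- rep.int(1:2, W2)
    op <- h + 2L * (w2 - 1L) + HW2 * (cc - 1L)
    i1[op] <- h + 2L * (2L * w2 - 2L) + HW * (cc - 1L)
  }
  list(i1 = i1, i2 = i1 + 2L, W_out = W2, HW_in = HW, HW_out = HW2)
}

glorot_uniform <- function(n_row, n_col, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_row * n_col, -lim, lim), n_row, n_col)
}

# ---- layer constructors -----------------------------------------------------

layer_conv <- function(W_in, C_in, K) {
  idx <- conv_indices(W_in, C_in)
  list(type = "conv", W_in = W_in, C_in = C_in, K = K,
       P = idx$P, colIdx = idx$colIdx, HW = idx$HW,
       W = glorot_uniform(9L * C_in, K, 9L * C_in, 9L * K),
       b = numeric(K), vW = matrix(0, 9L * C_in, K), vb = numeric(K),
       trainable = TRUE)
}

layer_pool <- function(W_in, C) {
  idx <- pool_indices(W_in, C)
  c(list(type = "pool", C = C, W_in = W_in), idx)
}

layer_dense <- function(d_in, d_out) {
  list(type = "dense", d_in = d_in, d_out = d_out,
       W = glorot_uniform(d_in, d_out, d_in, d_out), b = numeric(d_out),
       vW = matrix(0, d_in, d_out), vb = numeric(d_out), trainable = TRUE)
}

layer_relu <- function() list(type = "relu")
layer_dropout <- function(rate) list(type = "dropout", rate = rate)
layer_sigmoid <- function() list(type = "sigmoid")

# ---- model construction -----------------------------------------------------

#' Build an (untrained) FCN or CNN model
#'
#' FCN: `dense(256) -> ReLU -> dropout -> dense(128) -> ReLU -> dropout ->
#' dense(1) -> sigmoid`. CNN: the input row is reshaped to a `2 x S` grid
#' ([pair_to_grid()]), passed through `conv(k1, 3x3, ReLU) -> maxpool(1,2) ->
#' conv(k2, 3x3, ReLU) -> maxpool(1,2)`, flattened, then through the same
#' dense head. Weights are Glorot-uniform initialized under the config seed.
#'
#' @param config A [model_config()].
#' @param input_width Number of input features (`2S`; must be even for CNNs,
#'   with `S >= 4` so both pooling stages have width to pool).
#' @return An object of class `grn_fcn` or `grn_cnn` (both inherit `grn_nn`)
#'   with zero trained epochs. For CNNs, `$feature_dim` is the flatten width
#'   `2 * floor(floor(S/2)/2) * k2`.
#' @export
#' @examples
#' m <- build_model(model_config("fcn", seed = 1), input_width = 10)
#' nn_param_count(m)
build_model <- function(config, input_width) {
  stopifnot(inherits(config, "model_config"))
  input_width <- as.integer(input_width)
  du <- config$dense_units
  with_seed(derive_seed(config$seed, "init"), {
    if (config$model_family == "fcn") {
      layers <- list(layer_dense(input_width, du[1]), layer_relu(),
                     layer_dropout(config$dropout_rate),
                     layer_dense(du[1], du[2]), layer_relu(),
                     layer_dropout(config$dropout_rate),
                     layer_dense(du[2], 1L), layer_sigmoid())
      model <- list(config = config, input_width = input_width, layers = layers,
                    conv_prefix = 0L, feature_dim = NA_integer_, S = NA_integer_,
                    history = empty_history(), trained_epochs = 0L)
      class(model) <- c("grn_fcn", "grn_nn")
    } else {
      if (input_width %% 2 != 0) fail("CNN input width must be even, got %d", input_width)
      S <- input_width %/% 2L
      if (S < 4L) fail("CNN needs >= 4 samples per gene (got S = %d)", S)
      k <- config$conv_kernels
      W1 <- S
      W2 <- W1 %/% 2L
      W3 <- W2 %/% 2L
      layers <- list(layer_conv(W1, 1L, k[1]), layer_relu(), layer_pool(W1, k[1]),
                     layer_conv(W2, k[1], k[2]), layer_relu(), layer_pool(W2, k[2]))
      feature_dim <- 2L * W3 * k[2]
      layers <- c(layers, list(layer_dense(feature_dim, du[1]), layer_relu(),
                               layer_dropout(config$dropout_rate),
                               layer_dense(du[1], du[2]), layer_relu(),
                               layer_dropout(config$dropout_rate),
                               layer_dense(du[2], 1L), layer_sigmoid()))
      # input columns arrive as [TF block, target block]; the grid layout
      # interleaves them so position p = h + 2*(w-1)
      perm <- as.vector(rbind(seq_len(S), S + seq_len(S)))
      model <- list(config = config, input_width = input_width, layers = layers,
                    conv_prefix = 6L, feature_dim = feature_dim, S = S,
                    input_perm = perm, history = empty_history(),
                    trained_epochs = 0L)
      class(model) <- c("grn_cnn", "grn_nn")
    }
    model
  })
}

empty_history <- function() {
  data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
}

#' Total trainable parameter count of a model
#' @param model A `grn_nn` model.
#' @return Integer number of weights plus biases.
#' @export
nn_param_count <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

# ---- forward / backward -----------------------------------------------------

# forward pass; train = TRUE draws dropout masks from the current RNG stream.
# Returns list(p = sigmoid outputs, caches = per-layer caches, acts = per-layer
# inputs) with `upto` limiting the pass (used for feature extraction).
nn_forward <- function(model, X, train = FALSE, upto = length(model$layers)) {
  if (!is.null(model$input_perm)) X <- X[, model$input_perm, drop = FALSE]
  n <- nrow(X)
  caches <- vector("list", upto)
  for (i in seq_len(upto)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      X0 <- cbind(X, 0)
      M <- X0[, l$colIdx, drop = FALSE]
      dim(M) <- c(n * l$HW, 9L * l$C_in)
      Z <- M %*% l$W
      Z <- Z + matrix(l$b, nrow(Z), l$K, byrow = TRUE)
      dim(Z) <- c(n, l$HW * l$K)
      caches[[i]] <- list(M = M)
      X <- Z
    } else if (l$type == "pool") {
      A <- X[, l$i1, drop = FALSE]
      B <- X[, l$i2, drop = FALSE]
      mask <- A >= B
      caches[[i]] <- list(mask = mask, d_in = ncol(X))
      X <- pmax(A, B)
    } else if (l$type == "dense") {
      caches[[i]] <- list(A = X)
      X <- X %*% l$W + matrix(l$b, n, l$d_out, byrow = TRUE)
    } else if (l$type == "relu") {
      mask <- X > 0
      caches[[i]] <- list(mask = mask)
      X <- X * mask
    } else if (l$type == "dropout") {
      if (train && l$rate > 0) {
        mask <- matrix(stats::runif(length(X)) >= l$rate, nrow(X)) / (1 - l$rate)
        caches[[i]] <- list(mask = mask)
        X <- X * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (l$type == "sigmoid") {
      X <- 1 / (1 + exp(-X))
    }
  }
  list(out = X, caches = caches)
}

# backward pass from d(loss)/d(pre-sigmoid z); returns per-layer gradients
nn_backward <- function(model, caches, dZ) {
  L <- length(model$layers)
  grads <- vector("list", L)
  d <- dZ  # gradient at the input of the sigmoid (already chained)
  for (i in rev(seq_len(L))) {
    l <- model$layers[[i]]
    if (l$type == "sigmoid") {
      next  # chain rule applied by the loss
    } else if (l$type == "dense") {
      A <- caches[[i]]$A
      grads[[i]] <- list(dW = crossprod(A, d), db = colSums(d))
      d <- tcrossprod(d, l$W)
    } else if (l$type == "relu") {
      d <- d * caches[[i]]$mask
    } else if (l$type == "dropout") {
      if (!is.null(caches[[i]]$mask)) d <- d * caches[[i]]$mask
    } else if (l$type == "pool") {
      dX <- matrix(0, nrow(d), caches[[i]]$d_in)
      mask <- caches[[i]]$mask
      dX[, l$i1] <- d * mask
      dX[, l$i2] <- d * (!mask)
      d <- dX
    } else if (l$type == "conv") {
      n <- nrow(d)
      dZc <- d
      dim(dZc) <- c(n * l$HW, l$K)
      grads[[i]] <- list(dW = crossprod(caches[[i]]$M, dZc), db = colSums(dZc))
      dM <- tcrossprod(dZc, l$W)
      dim(dM) <- c(n, l$HW * 9L * l$C_in)
      dX <- matrix(0, n, l$HW * l$C_in)
      for (cc in seq_len(l$C_in)) {
        for (k in 1:9) {
          b_ix <- (cc - 1L) * 9L + k
          block <- dM[, ((b_ix - 1L) * l$HW + 1L):(b_ix * l$HW), drop = FALSE]
          valid <- which(!is.na(l$P[, k]))
          tcols <- l$P[valid, k] + l$HW * (cc - 1L)
          dX[, tcols] <- dX[, tcols] + block[, valid, drop = FALSE]
        }
      }
      d <- dX
    }
  }
  grads
}

# ---- losses -----------------------------------------------------------------

clamp_prob <- function(p) pmin(pmax(p, .prob_eps), 1 - .prob_eps)

#' Evaluate one of the eight supported loss functions
#'
#' Textbook formulas applied to sigmoid outputs `p` against 0/1 labels `y`
#' (hinge maps labels to -1/+1; Huber uses delta = 1; `msle` and `poisson`
#' use library-style formulas with a small probability clamp). Poisson and
#' msle are unconventional for binary targets; they are provided because the
#' loss-function benchmark sweeps all eight.
#'
#' @param name Loss name.
#' @param p Predicted probabilities in `[0, 1]`.
#' @param y 0/1 labels.
#' @return Mean loss (scalar).
#' @export
#' @examples
#' nn_loss("bce", c(0.9, 0.2, 0.6), c(1, 0, 1))
nn_loss <- function(name, p, y) {
  if (!name %in% .loss_names) {
    fail("unknown loss '%s'; valid losses: %s", name, paste(.loss_names, collapse = ", "))
  }
  pe <- clamp_prob(p)
  r <- p - y
  mean(switch(name,
    bce = -(y * log(pe) + (1 - y) * log(1 - pe)),
    hinge = pmax(1 - (2 * y - 1) * p, 0),
    mse = r^2,
    msle = (log1p(p) - log1p(y))^2,
    mae = abs(r),
    poisson = p - y * log(pe),
    huber = ifelse(abs(r) <= .huber_delta, 0.5 * r^2,
                   .huber_delta * (abs(r) - 0.5 * .huber_delta)),
    logcosh = log(cosh(r))
  ))
}

# d(mean loss)/dp, elementwise (the 1/n factor is applied by the caller)
nn_loss_dp <- function(name, p, y) {
  pe <- clamp_prob(p)
  r <- p - y
  switch(name,
    bce = (pe - y) / (pe * (1 - pe)),
    hinge = ifelse(1 - (2 * y - 1) * p > 0, -(2 * y - 1), 0),
    mse = 2 * r,
    msle = 2 * (log1p(p) - log1p(y)) / (1 + p),
    mae = sign(r),
    poisson = 1 - y / pe,
    huber = ifelse(abs(r) <= .huber_delta, r, .huber_delta * sign(r)),
    logcosh = tanh(r)
  )
}

# ---- training ---------------------------------------------------------------

rmsprop_update <- function(l, g, lr, rho = 0.9, eps = 1e-7) {
  l$vW <- rho * l$vW + (1 - rho) * g$dW^2
  l$vb <- rho * l$vb + (1 - rho) * g$db^2
  l$W <- l$W - lr * g$dW / (sqrt(l$vW) + eps)
  l$b <- l$b - lr * g$db / (sqrt(l$vb) + eps)
  l
}

#' Train an FCN or CNN model
#'
#' Minibatch RMSprop under the configuration stored in the model. Training is
#' reproducible for a fixed config seed on a single device: shuffling and
#' dropout masks are drawn from a seed derived from it (offset by the number
#' of epochs already trained, so resumed training continues the stream).
#'
#' @param model A `grn_nn` model from [build_model()] or [transfer_encoder()].
#' @param X Feature matrix (`pair_features` or plain matrix), rows = pairs.
#' @param y 0/1 labels, one per row.
#' @param epochs Number of epochs; defaults to the config value. Zero epochs
#'   returns the model untouched with no history appended.
#' @param freeze_conv If `TRUE`, convolutional layers are excluded from
#'   updates (transfer learning with a frozen encoder).
#' @return The trained model with `$history` extended by one row per epoch
#'   (training loss and threshold-0.5 accuracy).
#' @export
train_model <- function(model, X, y, epochs = model$config$epochs,
                        freeze_conv = FALSE) {
  stopifnot(inherits(model, "grn_nn"))
  X <- unclass_features(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) fail("X rows (%d) != y length (%d)", nrow(X), length(y))
  if (ncol(X) != model$input_width) {
    fail("X has %d columns but the model expects %d", ncol(X), model$input_width)
  }
  if (epochs == 0) return(model)
  if (length(unique(y)) < 2) fail("training labels contain a single class")
  if (freeze_conv) {
    for (i in seq_along(model$layers)) {
      if (model$layers[[i]]$type == "conv") model$layers[[i]]$trainable <- FALSE
    }
  }
  cfg <- model$config
  n <- nrow(X)
  bs <- min(cfg$batch_size, n)
  with_seed(derive_seed(cfg$seed, "train", model$trained_epochs), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = bs)
      ep_loss <- 0
      ep_correct <- 0
      for (s in starts) {
        ix <- ord[s:min(s + bs - 1, n)]
        Xb <- X[ix, , drop = FALSE]
        yb <- y[ix]
        fw <- nn_forward(model, Xb, train = TRUE)
        p <- as.vector(fw$out)
        ep_loss <- ep_loss + nn_loss(cfg$loss, p, yb) * length(ix)
        ep_correct <- ep_correct + sum((p >= 0.5) == (yb == 1))
        # chain through the sigmoid; BCE has the exact simplification p - y
        dz <- if (cfg$loss == "bce") (p - yb) else {
          nn_loss_dp(cfg$loss, p, yb) * p * (1 - p)
        }
        dz <- matrix(dz / length(ix), ncol = 1)
        grads <- nn_backward(model, fw$caches, dz)
        for (i in seq_along(model$layers)) {
          if (!is.null(grads[[i]]) && isTRUE(model$layers[[i]]$trainable)) {
            model$layers[[i]] <- rmsprop_update(model$layers[[i]], grads[[i]],
                                                cfg$learning_rate)
          }
        }
      }
      model$history <- rbind(model$history, data.frame(
        epoch = model$trained_epochs + ep,
        loss = ep_loss / n, accuracy = ep_correct / n))
    }
    model$trained_epochs <- model$trained_epochs + epochs
    model
  })
}

unclass_features <- function(X) {
  if (inherits(X, "pair_features")) {
    attr(X, "pairs") <- NULL
    attr(X, "labels") <- NULL
    attr(X, "n_dropped") <- NULL
    class(X) <- NULL
  }
  as.matrix(X)
}

#' Predicted probabilities from an FCN/CNN model
#'
#' Inference mode: dropout disabled, hence deterministic for fixed weights.
#'
#' @param object A `grn_nn` model.
#' @param newdata Feature matrix with `input_width` columns.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.grn_nn <- function(object, newdata, ...) {
  X <- unclass_features(newdata)
  if (ncol(X) != object$input_width) {
    fail("newdata has %d columns but the model expects %d", ncol(X), object$input_width)
  }
  as.vector(nn_forward(object, X, train = FALSE)$out)
}

#' Flattened convolutional activations of a CNN encoder
#'
#' Runs the convolutional prefix (conv/ReLU/pool twice) in inference mode and
#' returns the flattened feature map used as input to hybrid classifiers.
#'
#' @param encoder A trained `grn_cnn` model.
#' @param X Feature matrix (`n x 2S`).
#' @return Matrix of class `encoder_features` (`n x feature_dim`) with
#'   attribute `provenance` identifying the encoder.
#' @export
extract_features <- function(encoder, X) {
  if (!inherits(encoder, "grn_cnn")) {
    fail("feature extraction needs a CNN encoder, got %s", class(encoder)[1])
  }
  X <- unclass_features(X)
  if (ncol(X) != encoder$input_width) {
    fail("X has %d columns but the encoder expects %d", ncol(X), encoder$input_width)
  }
  F <- nn_forward(encoder, X, train = FALSE, upto = encoder$conv_prefix)$out
  stopifnot(ncol(F) == encoder$feature_dim)
  structure(F, class = c("encoder_features", "matrix", "array"),
            provenance = config_hash(encoder$config))
}

# ---- methods ----------------------------------------------------------------

#' @export
print.grn_nn <- function(x, ...) {
  cat(sprintf("%s model (%s loss): input width %d, %d parameters, %d epoch(s) trained\n",
              toupper(x$config$model_family), x$config$loss, x$input_width,
              nn_param_count(x), x$trained_epochs))
  if (inherits(x, "grn_cnn")) {
    cat(sprintf("Encoder: conv(%d) -> pool -> conv(%d) -> pool, flatten width %d\n",
                x$config$conv_kernels[1], x$config$conv_kernels[2], x$feature_dim))
  }
  invisible(x)
}

#' @export
summary.grn_nn <- function(object, ...) {
  print(object)
  if (nrow(object$history)) {
    cat("Final training loss/accuracy:\n")
    print(utils::tail(object$history, 3), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.grn_nn <- function(object, ...) {
  lapply(Filter(function(l) !is.null(l$W), object$layers),
         function(l) list(type = l$type, W = l$W, b = l$b))
}

#' Plot the training history of a model
#' @param x A trained `grn_nn`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.grn_nn <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) fail("model has no training history")
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss", ...)
  graphics::plot(h$epoch, h$accuracy, type = "l", xlab = "epoch",
                 ylab = "training accuracy", ylim = c(0, 1), ...)
  graphics::par(mfrow = c(1, 1))
  invisible(x)
}

#' Persist / restore a model
#'
#' Weights go to an RDS container and the configuration plus seeds to a JSON
#' sidecar (`<path>.json`), so runs are auditable without deserializing.
#'
#' @param model A `grn_nn` model.
#' @param path Output path for the weight container.
#' @return `save_model`: invisibly, `path`. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  sidecar <- list(class = class(model)[1], config = unclass(model$config),
                  trained_epochs = model$trained_epochs,
                  param_count = nn_param_count(model),
                  config_hash = config_hash(model$config))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
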