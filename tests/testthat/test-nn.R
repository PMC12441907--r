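test_that("pair rows reshape to 2 x S grids and back exactly", {
  expect_equal(pair_to_grid(c(1, 2, 3, 4, 5, 6)),
               matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE))
  set.seed(1)
  v <- rnorm(2 * 1253)  # a full compendium-sized pair row
  g <- pair_to_grid(v)
  expect_equal(dim(g), c(2, 1253))
  expect_identical(grid_to_pair(g), v)
  expect_error(pair_to_grid(1:5), "even length")
})

test_that("model configuration validates its invariants", {
  expect_error(model_config("fcn", loss = "xent"), "bce.*hinge.*mse")
  expect_error(model_config("cnn", learning_rate = 0), "learning_rate")
  expect_error(model_config("cnn", kernel_size = c(5, 5)), "fixed")
  cfg <- model_config("cnn")
  expect_equal(cfg$learning_rate, 3e-5)
  expect_equal(cfg$batch_size, 100L)
  expect_equal(cfg$dense_units, c(256L, 128L))
  expect_equal(cfg$epochs, 100L)
})

test_that("FCN parameter count matches closed-form shape arithmetic", {
  m <- build_model(model_config("fcn"), input_width = 2506)
  expected <- (2506 * 256 + 256) + (256 * 128 + 128) + (128 * 1 + 1)
  expect_equal(nn_param_count(m), expected)
})

test_that("CNN feature width matches an independent conv/pool shape trace", {
  # hand trace: 'same' conv keeps 2 x S; (1,2) pool halves S (floor); twice
  trace_dim <- function(S, k2) {
    w <- S
    w <- w %/% 2  # pool after conv1
    w <- w %/% 2  # pool after conv2
    2 * w * k2
  }
  for (S in c(8, 100, 101, 1253)) {
    for (k in list(c(8, 8), c(8, 16), c(16, 32))) {
      m <- build_model(model_config("cnn", conv_kernels = k), 2 * S)
      expect_equal(m$feature_dim, trace_dim(S, k[2]))
    }
  }
  # realized feature matrix agrees with the declared width
  m <- build_model(model_config("cnn", conv_kernels = c(4, 6), seed = 2), 2 * 25)
  set.seed(3)
  X <- matrix(rnorm(5 * 50), 5)
  expect_equal(dim(extract_features(m, X)), c(5, m$feature_dim))
  # conv parameter count: 3x3 kernels over C_in channels, plus biases
  conv_params <- (9 * 1 * 4 + 4) + (9 * 4 * 6 + 6)
  dense_in <- m$feature_dim
  dense_params <- (dense_in * 256 + 256) + (256 * 128 + 128) + (128 + 1)
  expect_equal(nn_param_count(m), conv_params + dense_params)
  expect_error(build_model(model_config("cnn"), 25), "even")
})

test_that("the eight losses reduce to their textbook forms on a toy vector", {
  p <- c(0.9, 0.2, 0.6)
  y <- c(1, 0, 1)
  expect_equal(nn_loss("bce", p, y), -mean(c(log(0.9), log(0.8), log(0.6))))
  # hinge on -1/+1 labels: max(1 - y* p, 0) with y* in {-1, 1}
  expect_equal(nn_loss("hinge", p, y), mean(c(1 - 0.9, 1 + 0.2, 1 - 0.6)))
  expect_equal(nn_loss("mse", p, y), mean(c(0.01, 0.04, 0.16)))
  expect_equal(nn_loss("mae", p, y), mean(c(0.1, 0.2, 0.4)))
  expect_equal(nn_loss("msle", p, y),
               mean((log1p(p) - log1p(y))^2))
  expect_equal(nn_loss("poisson", p, y), mean(p - y * log(p)))
  # |error| <= 1 everywhere, so Huber(delta = 1) is quadratic here
  expect_equal(nn_loss("huber", p, y), mean(0.5 * (p - y)^2))
  expect_equal(nn_loss("logcosh", p, y), mean(log(cosh(p - y))))
  expect_error(nn_loss("xent", p, y), "valid losses")
})

test_that("analytic gradients match finite differences for every loss", {
  grad_check <- function(family, loss, S = 8, n = 6) {
    cfg <- model_config(family, loss = loss, conv_kernels = c(3L, 2L),
                        dense_units = c(7L, 4L), dropout_rate = 0, seed = 42)
    width <- if (family == "cnn") 2 * S else S
    m <- build_model(cfg, width)
    set.seed(7)
    X <- matrix(rnorm(n * width), n)
    y <- rep(c(0, 1), length.out = n)
    fw <- grnlearn:::nn_forward(m, X, train = FALSE)
    p <- as.vector(fw$out)
    dz <- if (loss == "bce") (p - y) else grnlearn:::nn_loss_dp(loss, p, y) * p * (1 - p)
    grads <- grnlearn:::nn_backward(m, fw$caches, matrix(dz / n, ncol = 1))
    loss_at <- function(mm) {
      nn_loss(loss, as.vector(grnlearn:::nn_forward(mm, X, FALSE)$out), y)
    }
    worst <- 0
    for (li in seq_along(m$layers)) {
      if (is.null(grads[[li]])) next
      W <- m$layers[[li]]$W
      for (j in sample(length(W), min(6, length(W)))) {
        eps <- 1e-5
        m_hi <- m; m_hi$layers[[li]]$W[j] <- W[j] + eps
        m_lo <- m; m_lo$layers[[li]]$W[j] <- W[j] - eps
        num <- (loss_at(m_hi) - loss_at(m_lo)) / (2 * eps)
        worst <- max(worst, abs(num - grads[[li]]$dW[j]) /
                       max(1e-6, abs(num) + abs(grads[[li]]$dW[j])))
      }
    }
    worst
  }
  for (loss in c("bce", "hinge", "mse", "msle", "mae", "poisson", "huber", "logcosh")) {
    expect_lt(grad_check("fcn", loss), 1e-4)
  }
  expect_lt(grad_check("cnn", "bce"), 1e-4)
  expect_lt(grad_check("cnn", "mse"), 1e-4)
})

test_that("training fits linearly separable toy data", {
  toy <- toy_separable(200, seed = 3)
  cfg <- model_config("fcn", learning_rate = 1e-2, epochs = 100,
                      dense_units = c(16L, 8L), dropout_rate = 0, seed = 5)
  m <- build_model(cfg, 2)
  m <- train_model(m, toy$x, toy$y)
  expect_equal(nrow(m$history), 100)
  expect_gte(tail(m$history$accuracy, 1), 0.95)
  expect_lte(tail(m$history$loss, 1), m$history$loss[1])
  p <- predict(m, toy$x)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("zero-epoch training is the identity and bad labels error", {
  toy <- toy_separable(40)
  m <- build_model(model_config("fcn", dense_units = c(4L, 3L), seed = 1), 2)
  m0 <- train_model(m, toy$x, toy$y, epochs = 0)
  expect_identical(coef(m0), coef(m))
  expect_equal(nrow(m0$history), 0)
  expect_error(train_model(m, toy$x, rep(1, 40)), "single class")
  expect_error(train_model(m, toy$x, toy$y[-1]), "!=")
})

test_that("training is bitwise reproducible for a fixed seed", {
  toy <- toy_separable(60, seed = 9)
  run <- function() {
    cfg <- model_config("fcn", learning_rate = 1e-2, epochs = 3,
                        dense_units = c(8L, 4L), batch_size = 20, seed = 77)
    train_model(build_model(cfg, 2), toy$x, toy$y)
  }
  m1 <- run(); m2 <- run()
  expect_identical(coef(m1), coef(m2))
  expect_identical(m1$history, m2$history)
})

test_that("permuted labels give chance-level holdout accuracy", {
  toy <- toy_separable(300, seed = 12)
  set.seed(100)
  y_perm <- sample(toy$y)
  cfg <- model_config("fcn", learning_rate = 1e-2, epochs = 30,
                      dense_units = c(16L, 8L), seed = 8)
  m <- train_model(build_model(cfg, 2), toy$x[1:200, ], y_perm[1:200])
  acc <- mean((predict(m, toy$x[201:300, ]) >= 0.5) == (y_perm[201:300] == 1))
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

test_that("feature extraction is deterministic, shape-true, and CNN-only", {
  m <- build_model(model_config("cnn", conv_kernels = c(4, 4), seed = 3), 2 * 12)
  set.seed(4)
  X <- matrix(rnorm(7 * 24), 7)
  f1 <- extract_features(m, X)
  f2 <- extract_features(m, X)
  expect_identical(unclass(f1), unclass(f2))
  expect_equal(nrow(f1), 7)
  # zero input with zero biases propagates to zero features through ReLU
  expect_true(all(extract_features(m, matrix(0, 3, 24)) == 0))
  fcn <- build_model(model_config("fcn"), 24)
  expect_error(extract_features(fcn, X), "CNN encoder")
})

test_that("models survive a save/load round trip with a JSON sidecar", {
  toy <- toy_separable(40)
  cfg <- model_config("fcn", dense_units = c(4L, 3L), epochs = 2,
                      learning_rate = 1e-2, seed = 2)
  m <- train_model(build_model(cfg, 2), toy$x, toy$y)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$param_count, nn_param_count(m))
  back <- load_model(path)
  expect_identical(predict(back, toy$x), predict(m, toy$x))
})
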