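.classifier_families <- c("logistic_regression", "svm", "decision_tree", "knn",
                          "random_forest", "extra_trees", "adaboost",
                          "gradient_boosting", "bagging")

#' Specify a classical classifier
#'
#' @param family One of `"logistic_regression"`, `"svm"`, `"decision_tree"`,
#'   `"knn"`, `"random_forest"`, `"extra_trees"`, `"adaboost"`,
#'   `"gradient_boosting"`, `"bagging"`.
#' @param hyperparameters Named list overriding the family defaults (see
#'   Details).
#' @param seed Integer seed for stochastic families.
#' @return A list of class `classifier_spec`.
#' @details Defaults per family:
#'   logistic_regression: ridge-penalized (`lambda = 1e-3`);
#'   svm: radial kernel, `cost = 1`; decision_tree: `maxdepth = 10`,
#'   `cp = 0.01`; knn: `k = 5`, `metric = "manhattan"`; random_forest:
#'   `ntree = 200`; extra_trees: `num_trees = 200`; adaboost: `n_estimators =
#'   50`, `learning_rate = 1`, stumps; gradient_boosting: `nrounds = 100`,
#'   `eta = 0.1`, `max_depth = 3`; bagging: `n_estimators = 50`.
#' @export
classifier_spec <- function(family, hyperparameters = list(), seed = 1L) {
  if (!family %in% .classifier_families) {
    fail("unknown classifier family '%s'; valid families: %s", family,
         paste(.classifier_families, collapse = ", "))
  }
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

hp_get <- function(spec, name, default) {
  v <- spec$hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Fit a classical classifier on a feature matrix
#'
#' All nine families expose the same contract: `predict()` returns class-1
#' probabilities in `[0, 1]`. Margin-based families (SVM via Platt scaling,
#' AdaBoost via its normalized margin) use a monotone map to `[0, 1]`, so
#' rankings are unaffected.
#'
#' @param spec A [classifier_spec()].
#' @param X Feature matrix (rows = pairs); `encoder_features` or
#'   `pair_features` are accepted.
#' @param y 0/1 labels.
#' @return An object of class `grn_classifier`.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- strip_matrix(X)
  y <- as.integer(y)
  if (nrow(X) != length(y)) fail("X rows (%d) != y length (%d)", nrow(X), length(y))
  if (length(unique(y)) < 2) fail("training labels contain a single class")
  fit <- with_seed(spec$seed, switch(spec$family,
    logistic_regression = {
      lam <- hp_get(spec, "lambda", 1e-3)
      list(kind = "glmnet", lambda = lam,
           fit = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                lambda = lam))
    },
    svm = list(kind = "svm",
               fit = e1071::svm(X, factor(y, levels = c(0, 1)),
                                kernel = hp_get(spec, "kernel", "radial"),
                                cost = hp_get(spec, "cost", 1),
                                gamma = hp_get(spec, "gamma", 1 / ncol(X)),
                                probability = TRUE, scale = FALSE)),
    decision_tree = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      list(kind = "rpart",
           fit = rpart::rpart(.y ~ ., df, method = "class",
                              control = rpart::rpart.control(
                                maxdepth = hp_get(spec, "maxdepth", 10),
                                cp = hp_get(spec, "cp", 0.01),
                                minsplit = hp_get(spec, "minsplit", 20))))
    },
    knn = list(kind = "knn", X = X, y = y, k = hp_get(spec, "k", 5L),
               metric = hp_get(spec, "metric", "manhattan")),
    random_forest = {
      # randomForest loops forever when every feature is constant; drop
      # zero-variance columns and fall back to the class prior if none remain
      keep <- which(col_variance(X) > 0)
      if (!length(keep)) {
        list(kind = "prior", p1 = mean(y == 1))
      } else {
        list(kind = "rf", keep = keep,
             fit = randomForest::randomForest(
               X[, keep, drop = FALSE], factor(y, levels = c(0, 1)),
               ntree = hp_get(spec, "ntree", 200),
               mtry = hp_get(spec, "mtry", max(1, floor(sqrt(length(keep)))))))
      }
    },
    extra_trees = list(kind = "ranger",
                       fit = ranger::ranger(
                         x = X, y = factor(y, levels = c(0, 1)),
                         num.trees = hp_get(spec, "num_trees", 200),
                         mtry = hp_get(spec, "mtry", max(1, floor(sqrt(ncol(X))))),
                         splitrule = "extratrees", probability = TRUE,
                         num.threads = 1, seed = spec$seed)),
    adaboost = fit_adaboost(X, y,
                            n_estimators = hp_get(spec, "n_estimators", 50L),
                            learning_rate = hp_get(spec, "learning_rate", 1)),
    gradient_boosting = {
      dtr <- xgboost::xgb.DMatrix(X, label = y)
      list(kind = "xgb",
           fit = xgboost::xgb.train(
             params = list(objective = "binary:logistic",
                           eta = hp_get(spec, "eta", 0.1),
                           max_depth = hp_get(spec, "max_depth", 3),
                           nthread = 1, seed = spec$seed),
             data = dtr, nrounds = hp_get(spec, "nrounds", 100L),
             verbose = 0))
    },
    bagging = fit_bagging(X, y, n_estimators = hp_get(spec, "n_estimators", 50L))
  ))
  structure(list(spec = spec, fit = fit, n_features = ncol(X)),
            class = "grn_classifier")
}

col_variance <- function(X) {
  mu <- colMeans(X)
  colMeans(X^2) - mu^2
}

strip_matrix <- function(X) {
  X <- unclass_features(X)
  class(X) <- NULL
  attr(X, "provenance") <- NULL
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  X
}

# SAMME AdaBoost on rpart stumps (depth-1 trees)
fit_adaboost <- function(X, y, n_estimators, learning_rate) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  stumps <- list()
  alphas <- numeric()
  for (m in seq_len(n_estimators)) {
    fit <- rpart::rpart(.y ~ ., df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                       minsplit = 2, xval = 0))
    pred <- as.integer(as.character(predict(fit, df, type = "class")))
    err <- sum(w[pred != y])
    err <- min(max(err, 1e-10), 1 - 1e-10)
    if (err >= 0.5) break
    alpha <- learning_rate * log((1 - err) / err)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
  }
  if (!length(stumps)) fail("adaboost: no stump improved on chance")
  list(kind = "adaboost", stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, df) {
  score <- 0
  for (m in seq_along(fit$stumps)) {
    h <- as.integer(as.character(predict(fit$stumps[[m]], df, type = "class")))
    score <- score + fit$alphas[m] * (2 * h - 1)
  }
  margin <- score / sum(fit$alphas)  # in [-1, 1]
  (margin + 1) / 2
}

# bootstrap-aggregated rpart trees
fit_bagging <- function(X, y, n_estimators) {
  df <- as.data.frame(X)
  df$.y <- factor(y, levels = c(0, 1))
  trees <- lapply(seq_len(n_estimators), function(m) {
    ix <- sample.int(nrow(df), replace = TRUE)
    rpart::rpart(.y ~ ., df[ix, , drop = FALSE], method = "class",
                 control = rpart::rpart.control(cp = 0.01, xval = 0))
  })
  list(kind = "bagging", trees = trees)
}

#' Class-1 probabilities from a fitted classifier
#' @param object A `grn_classifier`.
#' @param newdata Feature matrix.
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.grn_classifier <- function(object, newdata, ...) {
  X <- strip_matrix(newdata)
  if (ncol(X) != object$n_features) {
    fail("newdata has %d features but the model was fitted on %d",
         ncol(X), object$n_features)
  }
  fit <- object$fit
  p <- switch(fit$kind,
    glmnet = as.vector(predict(fit$fit, X, s = fit$lambda, type = "response")),
    svm = {
      pr <- predict(fit$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    rpart = predict(fit$fit, as.data.frame(X), type = "prob")[, "1"],
    knn = predict_knn(fit, X),
    prior = rep(fit$p1, nrow(X)),
    rf = predict(fit$fit, X[, fit$keep, drop = FALSE], type = "prob")[, "1"],
    ranger = predict(fit$fit, data = X, num.threads = 1)$predictions[, "1"],
    adaboost = predict_adaboost(fit, as.data.frame(X)),
    xgb = predict(fit$fit, xgboost::xgb.DMatrix(X)),
    bagging = {
      probs <- vapply(fit$trees,
                      function(tr) predict(tr, as.data.frame(X), type = "prob")[, "1"],
                      numeric(nrow(X)))
      rowMeans(matrix(probs, nrow = nrow(X)))
    }
  )
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

# k-nearest-neighbour class-1 probability (Manhattan or Euclidean distance,
# ties in distance broken by training-row order)
predict_knn <- function(fit, X) {
  k <- min(fit$k, nrow(fit$X))
  vapply(seq_len(nrow(X)), function(i) {
    d <- if (fit$metric == "manhattan") {
      colSums(abs(t(fit$X) - X[i, ]))
    } else {
      sqrt(colSums((t(fit$X) - X[i, ])^2))
    }
    nn <- order(d)[seq_len(k)]
    mean(fit$y[nn])
  }, numeric(1))
}

#' @export
print.grn_classifier <- function(x, ...) {
  cat(sprintf("Classifier: %s (%d features)\n", x$spec$family, x$n_features))
  invisible(x)
}

#' Grid search over classifier hyperparameters by k-fold cross-validation
#'
#' Every grid point is scored by stratified k-fold cross-validated mean
#' accuracy (threshold 0.5) on shared folds; ties are broken by first-in-grid
#' order.
#'
#' @param spec A [classifier_spec()]; grid values override its
#'   hyperparameters.
#' @param grid Named list of hyperparameter value vectors.
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param folds Number of CV folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return A list with `best` (named list of winning hyperparameters),
#'   `best_index`, and `cv_table` (one row per grid point x fold).
#' @export
grid_search <- function(spec, grid, X, y, folds = 10L, seed = 1L) {
  if (!length(grid) || is.null(names(grid))) fail("grid must be a nonempty named list")
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  fold_id <- stratified_folds(y, folds, seed)
  rows <- vector("list", nrow(combos))
  means <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    hp <- utils::modifyList(spec$hyperparameters, as.list(combos[i, , drop = FALSE]))
    sp <- classifier_spec(spec$family, hp, spec$seed)
    acc <- fold_accuracies(sp, X, y, fold_id)
    means[i] <- mean(acc)
    rows[[i]] <- data.frame(grid_index = i, combos[i, , drop = FALSE],
                            fold = seq_along(acc), accuracy = acc,
                            row.names = NULL)
  }
  best_index <- which.max(means)  # first-in-grid order wins ties
  list(best = as.list(combos[best_index, , drop = FALSE]),
       best_index = best_index,
       mean_accuracy = means,
       cv_table = do.call(rbind, rows))
}

#' Default hyperparameter grids for grid search
#'
#' Reads the shipped grid declaration
#' (`inst/extdata/classifier_grids.json`), one named list of value vectors
#' per classifier family, suitable for [grid_search()].
#'
#' @param family Optional family name; if given, only that family's grid is
#'   returned.
#' @return A named list of grids (or a single grid).
#' @export
#' @examples
#' default_classifier_grids("knn")
default_classifier_grids <- function(family = NULL) {
  path <- system.file("extdata", "classifier_grids.json", package = "grnlearn")
  grids <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(family)) return(grids)
  if (is.null(grids[[family]])) fail("no shipped grid for family '%s'", family)
  grids[[family]]
}

fold_accuracies <- function(spec, X, y, fold_id) {
  X <- strip_matrix(X)
  vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    m <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr])
    p <- predict(m, X[!tr, , drop = FALSE])
    mean((p >= 0.5) == (y[!tr] == 1))
  }, numeric(1))
}
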