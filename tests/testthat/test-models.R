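# classifier families and the hybrid encoder -> classifier pipeline

test_that("all nine classifier families honor the probability contract", {
  toy <- toy_separable(120, seed = 21)
  holdout <- toy_separable(60, seed = 22)
  for (fam in c("logistic_regression", "svm", "decision_tree", "knn",
                "random_forest", "extra_trees", "adaboost",
                "gradient_boosting", "bagging")) {
    spec <- classifier_spec(fam, seed = 1)
    m <- fit_classifier(spec, toy$x, toy$y)
    p <- predict(m, holdout$x)
    expect_length(p, 60)
    expect_true(all(p >= 0 & p <= 1), label = fam)
    # strongly separable data: every family should beat chance comfortably
    expect_gte(roc_auc(p, holdout$y)$auc, 0.9)
  }
  expect_error(classifier_spec("naive_bayes"), "valid families")
})

test_that("stochastic families are reproducible under a fixed seed", {
  toy <- toy_separable(100, seed = 31)
  for (fam in c("random_forest", "extra_trees", "bagging", "gradient_boosting")) {
    p1 <- predict(fit_classifier(classifier_spec(fam, seed = 9), toy$x, toy$y), toy$x)
    p2 <- predict(fit_classifier(classifier_spec(fam, seed = 9), toy$x, toy$y), toy$x)
    expect_identical(p1, p2, label = fam)
  }
})

test_that("1-nearest-neighbor memorizes its training set", {
  toy <- toy_separable(50, seed = 41)
  m <- fit_classifier(classifier_spec("knn", list(k = 1)), toy$x, toy$y)
  p <- predict(m, toy$x)
  expect_equal(mean((p >= 0.5) == (toy$y == 1)), 1.0)
})

test_that("constant features yield chance-level AUC by the tie convention", {
  x <- matrix(1, 80, 4)
  y <- rep(c(0, 1), 40)
  m <- fit_classifier(classifier_spec("random_forest", seed = 2), x, y)
  p <- predict(m, x)
  expect_equal(roc_auc(p, y)$auc, 0.5, tolerance = 0.05)
})

test_that("hybrid classifier on strong-signal encoder features reaches high AUC", {
  sim <- small_sim_xy(seed = 51, n_samples = 100, signal = 3, noise_sd = 0.3,
                      n_pos = 150, n_genes = 300, n_tfs = 20)
  sp <- split_pair_matrix(sim$x, sim$y, seed = 52)
  enc <- build_model(model_config("cnn", learning_rate = 1e-3, epochs = 20,
                                  seed = 53), ncol(sim$x))
  enc <- train_model(enc, sp$x_train, sp$y_train)
  ftr <- extract_features(enc, sp$x_train)
  fte <- extract_features(enc, sp$x_test)
  aucs <- vapply(1:3, function(s) {
    m <- fit_hybrid(ftr, sp$y_train, classifier_spec("random_forest", seed = s))
    roc_auc(predict(m, fte), sp$y_test)$auc
  }, numeric(1))
  expect_true(all(aucs >= 0.9))
})

test_that("train_hybrid wires encoder and classifier together", {
  sim <- small_sim_xy(seed = 61, n_pos = 40, n_genes = 120, n_tfs = 10)
  sp <- split_pair_matrix(sim$x, sim$y, seed = 62)
  hm <- train_hybrid(sp$x_train, sp$y_train,
                     model_config("cnn", learning_rate = 1e-3, epochs = 5, seed = 63),
                     classifier_spec("random_forest", seed = 63))
  p <- predict(hm, sp$x_test)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_hybrid(sp$x_train, sp$y_train, model_config("fcn"),
                            classifier_spec("svm")), "must be a CNN")
})

test_that("grid search scores every point by shared-fold CV and breaks ties first-in-grid", {
  toy <- toy_separable(100, seed = 71)
  spec <- classifier_spec("knn")
  single <- grid_search(spec, list(k = 5), toy$x, toy$y, folds = 5, seed = 1)
  expect_equal(single$best$k, 5)
  expect_equal(nrow(single$cv_table), 5)  # folds rows for the single point

  # k = 1 memorizes cleanly separable data; k = 99 nearly votes the prior
  two <- grid_search(spec, list(k = c(1, 99)), toy$x, toy$y, folds = 10, seed = 1)
  expect_equal(two$best$k, 1)
  expect_equal(sum(two$cv_table$k == 1), 10)  # 10 per-fold scores per point
  expect_equal(sum(two$cv_table$k == 99), 10)

  expect_error(grid_search(spec, list(), toy$x, toy$y), "nonempty")
  tiny_y <- rep(c(0, 1), c(3, 97))
  expect_error(grid_search(spec, list(k = 1), toy$x, tiny_y, folds = 10),
               "minority class")
})

test_that("shipped hyperparameter grids load and drive a grid search", {
  grids <- default_classifier_grids()
  expect_setequal(names(grids),
                  c("logistic_regression", "svm", "decision_tree", "knn",
                    "random_forest", "extra_trees", "adaboost",
                    "gradient_boosting", "bagging"))
  knn_grid <- default_classifier_grids("knn")
  expect_true(all(c("k", "metric") %in% names(knn_grid)))
  toy <- toy_separable(60, seed = 3)
  gs <- grid_search(classifier_spec("decision_tree"),
                    lapply(default_classifier_grids("decision_tree"), head, 2),
                    toy$x, toy$y, folds = 3, seed = 1)
  expect_length(gs$mean_accuracy, 4)
  expect_error(default_classifier_grids("naive_bayes"), "no shipped grid")
})

test_that("kernel grid experiment fills an accuracy matrix deterministically", {
  sim <- small_sim_xy(seed = 81, n_genes = 250, n_tfs = 15, n_samples = 40,
                      n_pos = 100, signal = 3, noise_sd = 0.3)
  sp <- split_pair_matrix(sim$x, sim$y, seed = 82)
  cfg <- model_config("cnn", learning_rate = 1e-3, epochs = 40,
                      batch_size = 40, seed = 83)
  acc <- kernel_grid_experiment(c(4, 8),
                                list(x = sp$x_train, y = sp$y_train),
                                list(x = sp$x_test, y = sp$y_test), cfg)
  expect_equal(dim(acc), c(2, 2))
  expect_true(all(acc >= 0 & acc <= 1))
  expect_true(all(acc >= 0.8))  # strong planted signal
  seeds <- attr(acc, "seeds")
  expect_equal(dim(seeds), c(2, 2))
  # repeating one cell with its recorded seed reproduces the value
  cfg2 <- cfg
  cfg2$conv_kernels <- c(4L, 8L)
  cfg2$seed <- as.integer(seeds[1, 2])
  m <- train_model(build_model(cfg2, ncol(sim$x)), sp$x_train, sp$y_train)
  acc_cell <- mean((predict(m, sp$x_test) >= 0.5) == (sp$y_test == 1))
  expect_identical(acc_cell, acc[1, 2])
})
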