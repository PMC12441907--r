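#' Confusion-matrix metrics at a score threshold
#'
#' Applies the standard formulas verbatim: accuracy = (TP + TN) / total,
#' precision = TP / (TP + FP), recall = TP / (TP + FN), specificity =
#' TN / (TN + FP), F1 = 2 * precision * recall / (precision + recall).
#' Ratios with a zero denominator are reported as `NA` with a warning, never
#' silently coerced to 0.
#'
#' @param scores Predicted scores in `[0, 1]`.
#' @param labels 0/1 labels of equal length.
#' @param threshold Score cut-off for calling a prediction positive
#'   (default 0.5).
#' @return A list of class `metrics_report` with `counts` (TP, FP, TN, FN)
#'   and `accuracy`, `precision`, `recall`, `specificity`, `f1`, `threshold`.
#' @export
#' @examples
#' confusion_metrics(c(0.9, 0.8, 0.3, 0.6), c(1, 0, 0, 1))
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) {
    fail("scores length (%d) != labels length (%d)", length(scores), length(labels))
  }
  pred <- scores >= threshold
  pos <- labels == 1
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator); reported as NA", what),
              call. = FALSE)
      NA_real_
    } else num / den
  }
  accuracy <- (tp + tn) / length(labels)
  precision <- safe_ratio(tp, tp + fp, "precision")
  recall <- safe_ratio(tp, tp + fn, "recall")
  specificity <- safe_ratio(tn, tn + fp, "specificity")
  f1 <- if (is.na(precision) || is.na(recall)) {
    warning("F1 undefined; reported as NA", call. = FALSE)
    NA_real_
  } else if (precision + recall == 0) {
    warning("F1 undefined (precision + recall = 0); reported as NA", call. = FALSE)
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 accuracy = accuracy, precision = precision, recall = recall,
                 specificity = specificity, f1 = f1, threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Confusion counts (threshold %.3g): TP=%d FP=%d TN=%d FN=%d\n",
              x$threshold, x$counts["TP"], x$counts["FP"], x$counts["TN"],
              x$counts["FN"]))
  for (m in c("accuracy", "precision", "recall", "specificity", "f1")) {
    cat(sprintf("  %-11s %s\n", m,
                if (is.na(x[[m]])) "NA (undefined)" else sprintf("%.4f", x[[m]])))
  }
  invisible(x)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps thresholds over the unique scores, yielding (FPR, TPR) points from
#' (0, 0) to (1, 1); the trapezoidal area equals the Mann-Whitney concordance
#' probability with half credit for ties.
#'
#' @param scores Predicted scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return A list of class `roc_curve` with `fpr`, `tpr` (ordered points)
#'   and `auc`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc  # 0.75
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    fail("scores length (%d) != labels length (%d)", length(scores), length(labels))
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) fail("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each distinct score (ties grouped)
  last_of_group <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y == 1)[last_of_group]
  fp <- cumsum(y == 0)[last_of_group]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "FPR (1 - specificity)",
                 ylab = "TPR (recall)", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Write ROC points as a two-column TSV
#' @param roc A `roc_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_roc_points <- function(roc, path) {
  write_tsv_atomic(data.frame(fpr = roc$fpr, tpr = roc$tpr), path,
                   c(auc = sprintf("%.6f", roc$auc)))
}

#' Stratified fold assignment
#'
#' @param y 0/1 labels.
#' @param folds Number of folds; must not exceed the minority class size.
#' @param seed Integer seed.
#' @return Integer vector of fold IDs in `1:folds`, one per row, with class
#'   counts per fold balanced to within one.
#' @export
stratified_folds <- function(y, folds, seed = 1L) {
  folds <- as.integer(folds)
  if (folds < 2) fail("folds must be >= 2")
  if (min(table(y)) < folds) {
    fail("folds (%d) exceeds the minority class size (%d)", folds, min(table(y)))
  }
  id <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      ix <- which(y == cls)
      id[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    }
  })
  id
}

#' Stratified k-fold cross-validation of a classifier or network
#'
#' Each row is scored exactly once, by the model trained on the other folds;
#' fold assignment is reproducible by seed.
#'
#' @param model_spec A [classifier_spec()] or a [model_config()].
#' @param X Feature matrix.
#' @param y 0/1 labels.
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling the fold assignment.
#' @return Numeric vector of per-fold accuracies (threshold 0.5), with the
#'   fold assignment attached as attribute `fold_id`.
#' @export
cross_validate <- function(model_spec, X, y, folds = 10L, seed = 1L) {
  fold_id <- stratified_folds(y, folds, seed)
  X <- strip_matrix(X)
  acc <- vapply(sort(unique(fold_id)), function(f) {
    tr <- fold_id != f
    p <- if (inherits(model_spec, "classifier_spec")) {
      m <- fit_classifier(model_spec, X[tr, , drop = FALSE], y[tr])
      predict(m, X[!tr, , drop = FALSE])
    } else if (inherits(model_spec, "model_config")) {
      m <- build_model(model_spec, ncol(X))
      m <- train_model(m, X[tr, , drop = FALSE], y[tr])
      predict(m, X[!tr, , drop = FALSE])
    } else {
      fail("model_spec must be a classifier_spec or model_config")
    }
    mean((p >= 0.5) == (y[!tr] == 1))
  }, numeric(1))
  attr(acc, "fold_id") <- fold_id
  acc
}

#' Combined metrics report (confusion metrics plus AUC)
#'
#' @inheritParams confusion_metrics
#' @return A `metrics_report` with an additional `auc` element.
#' @export
evaluate_predictions <- function(scores, labels, threshold = 0.5) {
  rep <- confusion_metrics(scores, labels, threshold)
  rep$auc <- roc_auc(scores, labels)$auc
  rep
}
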