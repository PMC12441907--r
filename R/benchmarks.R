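# Self-contained end-to-end benchmark harnesses on synthetic data. These are
# the package's own reference experiments: signal recovery by the hybrid
# pipeline, no-leakage label-permutation controls, and planted-regulator
# ranking. Simulation sizes follow the package's standard study conditions
# (see the methods vignette).

#' Hybrid-pipeline signal-recovery benchmark
#'
#' Generates a planted-signal compendium (default: coupling 2, noise SD 0.5,
#' 200 samples, 1,000 positive plus 1,000 sampled negative pairs), trains the
#' hybrid CNN-encoder / random-forest pipeline on the 80\% stratified
#' training split, and reports holdout AUC. Optionally the same data is
#' scored by the plain (raw-feature) classifier, and labels can be permuted
#' as a no-leakage control.
#'
#' @param seed Integer seed driving data generation, splits, and training.
#' @param signal,noise_sd,n_samples,n_pairs Generator conditions.
#' @param epochs Encoder training epochs (desk-scale default 15).
#' @param learning_rate Encoder learning rate (desk-scale default 1e-3).
#' @param classifier Classifier family for both hybrid and plain fits.
#' @param permute_labels If `TRUE`, training and test labels are randomly
#'   permuted (the no-signal control).
#' @param include_plain If `TRUE`, also fit the classifier on raw pair
#'   features.
#' @return A list with `hybrid_auc`, `hybrid_f1`, and (optionally)
#'   `plain_auc`, plus the problem size `n`.
#' @export
hybrid_benchmark <- function(seed, signal = 2, noise_sd = 0.5,
                             n_samples = 200L, n_pairs = 1000L,
                             epochs = 15L, learning_rate = 1e-3,
                             classifier = "random_forest",
                             permute_labels = FALSE, include_plain = FALSE) {
  spec <- synthetic_spec(n_genes = n_pairs + 200L, n_tfs = 100L,
                         n_samples = n_samples, n_positive_pairs = n_pairs,
                         signal = signal, noise_sd = noise_sd,
                         seed = derive_seed(seed, "bench_data"))
  ds <- generate_dataset(spec)
  neg <- sample_negative_pairs(ds$tf_ids, gene_ids(ds$compendium),
                               ds$positives, n_pairs,
                               seed = derive_seed(seed, "bench_neg"))
  pairs <- rbind(as.data.frame(ds$positives), as.data.frame(neg))
  class(pairs) <- c("pair_set", "data.frame")
  x <- build_feature_matrix(pairs, ds$compendium)
  y <- feature_labels(x)
  if (permute_labels) {
    y <- with_seed(derive_seed(seed, "bench_perm"), sample(y))
  }
  sp <- split_pair_matrix(x, y, seed = derive_seed(seed, "bench_split"))
  cfg <- model_config("cnn", learning_rate = learning_rate, epochs = epochs,
                      seed = derive_seed(seed, "bench_enc"))
  cls <- classifier_spec(classifier, seed = derive_seed(seed, "bench_cls"))
  hm <- train_hybrid(sp$x_train, sp$y_train, cfg, cls)
  p <- predict(hm, sp$x_test)
  out <- list(hybrid_auc = roc_auc(p, sp$y_test)$auc,
              hybrid_f1 = {
                f1 <- suppressWarnings(confusion_metrics(p, sp$y_test)$f1)
                ifelse(is.na(f1), 0, f1)
              },
              n = nrow(x))
  if (include_plain) {
    pm <- fit_classifier(cls, sp$x_train, sp$y_train)
    out$plain_auc <- roc_auc(predict(pm, sp$x_test), sp$y_test)$auc
  }
  out
}

#' Planted-master-regulator ranking benchmark
#'
#' Generates a compendium in which one TF (the most prolific regulator)
#' drives a pathway of its own targets, trains the hybrid pipeline on all
#' labeled pairs, scores the full TF x pathway cross-pairing, and ranks TFs
#' by top-k frequency.
#'
#' @param seed Integer seed.
#' @param n_pathway Number of pathway genes taken from the master's targets.
#' @param top_k Top-k cut for the frequency ranking.
#' @param epochs,learning_rate Encoder training settings.
#' @return A list with `master` (TF ID), `rank` (its rank), `top1`
#'   (logical), `freq_conserved` (frequency-conservation check), and `n`
#'   (number of scored pairs).
#' @export
ranking_benchmark <- function(seed, n_pathway = 10L, top_k = 50L,
                              epochs = 15L, learning_rate = 1e-3) {
  spec <- synthetic_spec(n_genes = 600L, n_tfs = 40L, n_samples = 100L,
                         n_positive_pairs = 400L,
                         seed = derive_seed(seed, "rank_data"))
  ds <- generate_dataset(spec)
  tab <- sort(table(ds$positives$tf_id), decreasing = TRUE)
  master <- names(tab)[1]
  pathway <- ds$positives$target_id[ds$positives$tf_id == master][seq_len(n_pathway)]
  neg <- sample_negative_pairs(ds$tf_ids, gene_ids(ds$compendium),
                               ds$positives, nrow(ds$positives),
                               seed = derive_seed(seed, "rank_neg"))
  pairs <- rbind(as.data.frame(ds$positives), as.data.frame(neg))
  class(pairs) <- c("pair_set", "data.frame")
  x <- build_feature_matrix(pairs, ds$compendium)
  cfg <- model_config("cnn", learning_rate = learning_rate, epochs = epochs,
                      seed = derive_seed(seed, "rank_enc"))
  hm <- train_hybrid(x, feature_labels(x), cfg,
                     classifier_spec("random_forest",
                                     seed = derive_seed(seed, "rank_cls")))
  cp <- cross_pairs(ds$tf_ids, pathway)
  xc <- build_feature_matrix(cp, ds$compendium)
  sc <- scored_pairs(attr(xc, "pairs"), predict(hm, xc), "hybrid_rf")
  rk <- rank_tfs_by_frequency(sc, top_k = top_k)
  list(master = master,
       rank = rk$rank[rk$tf_id == master],
       top1 = rk$tf_id[1] == master,
       freq_conserved = sum(rk$frequency) == min(top_k, nrow(sc)),
       n = nrow(sc))
}
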