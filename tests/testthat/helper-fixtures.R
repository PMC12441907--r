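# Shared fixture builders. All data is generated in code at test time.

# small raw-count compendium for IO / TMM tests
tiny_count_matrix <- function(n_genes = 50, n_samples = 4, lambda = 20, seed = 1) {
  set.seed(seed)
  matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

# labeled pair feature matrix from a small planted-signal simulation;
# returns list(x, y, pairs, ds)
small_sim_xy <- function(seed = 1, n_genes = 200, n_tfs = 20, n_samples = 40,
                         n_pos = 80, signal = 2, noise_sd = 0.5) {
  spec <- synthetic_spec(n_genes = n_genes, n_tfs = n_tfs,
                         n_samples = n_samples, n_positive_pairs = n_pos,
                         signal = signal, noise_sd = noise_sd, seed = seed)
  ds <- generate_dataset(spec)
  neg <- sample_negative_pairs(ds$tf_ids, gene_ids(ds$compendium),
                               ds$positives, n_pos,
                               seed = derive_seed(seed, "helper_neg"))
  pairs <- rbind(as.data.frame(ds$positives), as.data.frame(neg))
  class(pairs) <- c("pair_set", "data.frame")
  x <- build_feature_matrix(pairs, ds$compendium)
  list(x = x, y = feature_labels(x), pairs = pairs, ds = ds)
}

# (nearly) separable two-feature toy classification set; gap = 3 puts the
# Bayes accuracy above 98%
toy_separable <- function(n = 200, seed = 1, gap = 3) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  x <- cbind(rnorm(n) + gap * y, rnorm(n) - gap * y)
  colnames(x) <- c("f1", "f2")
  list(x = x, y = y)
}

# brute-force TMM oracle: explicit sorting for both trims, explicit loop for
# the weighted mean; independent of the rank-based implementation
tmm_oracle_factors <- function(y, logratio_trim = 0.3, abs_expr_trim = 0.05) {
  lib <- colSums(y)
  uq <- sapply(seq_len(ncol(y)), function(k) {
    quantile(y[y[, k] > 0, k] / lib[k], 0.75, names = FALSE)
  })
  ref <- which.min(abs(uq - mean(uq)))
  gid_all <- rownames(y)
  f <- sapply(seq_len(ncol(y)), function(k) {
    use <- which(y[, k] > 0 & y[, ref] > 0)
    yk <- y[use, k]; yr <- y[use, ref]; gid <- gid_all[use]
    M <- log2((yk / lib[k]) / (yr / lib[ref]))
    A <- 0.5 * log2((yk / lib[k]) * (yr / lib[ref]))
    w <- 1 / ((lib[k] - yk) / (lib[k] * yk) + (lib[ref] - yr) / (lib[ref] * yr))
    n <- length(M)
    ord_m <- order(M, gid)
    keep_m <- ord_m[(floor(n * logratio_trim) + 1):(n - floor(n * logratio_trim))]
    ord_a <- order(A, gid)
    keep_a <- ord_a[(floor(n * abs_expr_trim) + 1):(n - floor(n * abs_expr_trim))]
    keep <- intersect(keep_m, keep_a)
    s_num <- 0; s_den <- 0
    for (i in keep) {
      s_num <- s_num + w[i] * M[i]
      s_den <- s_den + w[i]
    }
    2^(s_num / s_den)
  })
  unname(f / exp(mean(log(f))))
}
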