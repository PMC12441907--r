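#' Score TF-pathway pairs and table of scored pairs
#'
#' @param pairs A `pair_set` (typically from [cross_pairs()]).
#' @param score Numeric score per pair (finite).
#' @param scorer Tag identifying the scorer (model ID or `"spearman"`).
#' @return A data frame of class `scored_pairs` with columns
#'   `tf_id, target_id, score`.
#' @export
scored_pairs <- function(pairs, score, scorer = "model") {
  if (nrow(pairs) != length(score)) {
    fail("pairs (%d) and scores (%d) differ in length", nrow(pairs), length(score))
  }
  df <- data.frame(tf_id = pairs$tf_id, target_id = pairs$target_id,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  attr(df, "scorer") <- scorer
  class(df) <- c("scored_pairs", "data.frame")
  df
}

#' Rank TFs by frequency among the top-k scored pairs
#'
#' Pairs are sorted by score descending (ties broken deterministically by
#' `tf_id` then `target_id`), the top `top_k` retained, and occurrences
#' counted per TF. The table is sorted by frequency descending, ties by first
#' appearance in the score ordering. Frequencies always sum to
#' `min(top_k, n_pairs)`.
#'
#' @param scored A `scored_pairs` table (or data frame with `tf_id`,
#'   `target_id`, `score`).
#' @param top_k Number of top pairs considered (default 1000).
#' @return A data frame of class `ranked_tf_table` with columns
#'   `rank, tf_id, frequency`, and attributes `top_k` and `n_pairs`.
#' @export
#' @examples
#' sc <- data.frame(tf_id = c("t1", "t2", "t1"), target_id = c("g1", "g1", "g2"),
#'                  score = c(0.9, 0.8, 0.1))
#' rank_tfs_by_frequency(sc, top_k = 2)
rank_tfs_by_frequency <- function(scored, top_k = 1000L) {
  if (!nrow(scored)) fail("scored pair table is empty")
  if (top_k <= 0) fail("top_k must be positive, got %d", top_k)
  if (anyNA(scored$score)) fail("scores contain NA; score the pairs first")
  ord <- order(-scored$score, scored$tf_id, scored$target_id)
  taken <- scored[ord, , drop = FALSE][seq_len(min(top_k, nrow(scored))), , drop = FALSE]
  first_seen <- !duplicated(taken$tf_id)
  tf_order <- taken$tf_id[first_seen]
  freq <- table(factor(taken$tf_id, levels = tf_order))
  out_ord <- order(-as.integer(freq), seq_along(freq))
  res <- data.frame(rank = seq_along(out_ord),
                    tf_id = names(freq)[out_ord],
                    frequency = as.integer(freq)[out_ord],
                    stringsAsFactors = FALSE)
  attr(res, "top_k") <- as.integer(top_k)
  attr(res, "n_pairs") <- nrow(scored)
  class(res) <- c("ranked_tf_table", "data.frame")
  res
}

#' @export
print.ranked_tf_table <- function(x, ...) {
  cat(sprintf("TF frequency ranking (top %d of %d pairs)\n",
              attr(x, "top_k"), attr(x, "n_pairs")))
  print.data.frame(utils::head(x, 10), row.names = FALSE)
  if (nrow(x) > 10) cat(sprintf("... %d more TFs\n", nrow(x) - 10))
  invisible(x)
}

#' Score pairs by absolute Spearman rank correlation
#'
#' The baseline statistical scorer: `|rho|` between the TF and target
#' expression vectors over all compendium samples, with average-rank ties.
#' Pairs involving a constant expression vector get an `NA` score with a
#' warning.
#'
#' @param pairs A `pair_set`; all genes must be present in the compendium.
#' @param comp An `expr_compendium`.
#' @return A `scored_pairs` table with scorer tag `"spearman"`.
#' @export
spearman_score_pairs <- function(pairs, comp) {
  stopifnot(inherits(comp, "expr_compendium"))
  genes <- unique(c(pairs$tf_id, pairs$target_id))
  missing <- setdiff(genes, rownames(comp$values))
  if (length(missing)) {
    fail("gene(s) absent from the compendium: %s",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  V <- comp$values[genes, , drop = FALSE]
  R <- t(apply(V, 1, rank))  # average-rank ties
  mu <- rowMeans(R)
  Z <- R - mu
  sd_ <- sqrt(rowSums(Z^2))
  const <- sd_ == 0
  if (any(const)) {
    warning(sprintf("constant expression vector(s): %s; their pair scores are NA",
                    paste(utils::head(rownames(V)[const], 5), collapse = ", ")),
            call. = FALSE)
  }
  ti <- match(pairs$tf_id, genes)
  gi <- match(pairs$target_id, genes)
  rho <- rowSums(Z[ti, , drop = FALSE] * Z[gi, , drop = FALSE]) /
    (sd_[ti] * sd_[gi])
  rho[const[ti] | const[gi]] <- NA_real_
  scored_pairs(pairs, abs(rho), scorer = "spearman")
}

#' Known-TF recovery within ranked intervals
#'
#' Counts how many TFs of a known-regulator set fall into each rank interval
#' (1-5, 6-10, ..., up to `top_n`) of a ranked TF table.
#'
#' @param ranked A `ranked_tf_table`.
#' @param known_ids Character vector of known regulator TF IDs.
#' @param top_n Number of top ranks summarized (default 50; must be a
#'   multiple of `bin_width`).
#' @param bin_width Interval width (default 5).
#' @return A data frame `(interval, count)` with attribute `total` (known
#'   TFs within the top `top_n`).
#' @export
known_tf_recovery <- function(ranked, known_ids, top_n = 50L, bin_width = 5L) {
  if (top_n %% bin_width != 0) {
    fail("top_n (%d) must be a multiple of bin_width (%d)", top_n, bin_width)
  }
  top <- utils::head(ranked, top_n)
  hit_rank <- top$rank[top$tf_id %in% known_ids]
  n_bins <- top_n %/% bin_width
  bin <- findInterval(hit_rank, seq(1, top_n + 1, by = bin_width),
                      rightmost.closed = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  lo <- seq(1, top_n, by = bin_width)
  res <- data.frame(interval = sprintf("%d-%d", lo, lo + bin_width - 1),
                    count = counts, stringsAsFactors = FALSE)
  attr(res, "total") <- length(hit_rank)
  res
}

#' Write a ranked TF table as TSV
#' @param ranked A `ranked_tf_table`.
#' @param path Output path.
#' @param header Optional named character vector of header comments.
#' @return Invisibly, `path`.
#' @export
write_ranked_tf_table <- function(ranked, path, header = character()) {
  write_tsv_atomic(as.data.frame(ranked), path,
                   c(header, top_k = as.character(attr(ranked, "top_k"))))
}
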