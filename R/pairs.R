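#' Construct a labeled TF-target pair set
#'
#' @param tf_id,target_id Character vectors of equal length.
#' @param label Integer vector of 0/1 labels, or `NA` for unlabeled pairs.
#' @param source Provenance tag per pair: one of `"curated"`,
#'   `"homolog_mapped"`, `"sampled_negative"`, `"cross_pair"`.
#' @param species Optional species name, stored as an attribute.
#' @return A data frame of class `pair_set` with columns
#'   `tf_id, target_id, label, source`.
#' @export
pair_set <- function(tf_id, target_id, label = NA_integer_,
                     source = "curated", species = NA_character_) {
  tf_id <- as.character(tf_id)
  target_id <- as.character(target_id)
  if (length(tf_id) != length(target_id)) {
    fail("tf_id and target_id lengths differ (%d vs %d)",
         length(tf_id), length(target_id))
  }
  label <- as.integer(rep_len(label, length(tf_id)))
  if (!all(label %in% c(0L, 1L, NA_integer_))) fail("labels must be 0, 1 or NA")
  source <- rep_len(as.character(source), length(tf_id))
  ok <- source %in% c("curated", "homolog_mapped", "sampled_negative", "cross_pair")
  if (!all(ok)) fail("unknown source tag(s): %s", paste(unique(source[!ok]), collapse = ", "))
  df <- data.frame(tf_id = tf_id, target_id = target_id, label = label,
                   source = source, stringsAsFactors = FALSE)
  for (lab in c(0L, 1L)) {
    sub <- df[!is.na(df$label) & df$label == lab, ]
    key <- paste(sub$tf_id, sub$target_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- sub[duplicated(key), ][1, ]
      fail("duplicate pair within label class %d: (%s, %s)", lab, d$tf_id, d$target_id)
    }
  }
  pos_key <- with(df, paste(tf_id, target_id, sep = "\r")[!is.na(label) & label == 1])
  neg_key <- with(df, paste(tf_id, target_id, sep = "\r")[!is.na(label) & label == 0])
  if (length(intersect(pos_key, neg_key))) {
    fail("pair(s) present with both labels: %s",
         strsplit(intersect(pos_key, neg_key)[1], "\r")[[1]][1])
  }
  attr(df, "species") <- species
  class(df) <- c("pair_set", "data.frame")
  df
}

#' @export
print.pair_set <- function(x, ...) {
  n_pos <- sum(x$label == 1, na.rm = TRUE)
  n_neg <- sum(x$label == 0, na.rm = TRUE)
  n_un <- sum(is.na(x$label))
  cat(sprintf("Pair set: %d pairs (%d positive, %d negative, %d unlabeled)\n",
              nrow(x), n_pos, n_neg, n_un))
  if (!is.na(attr(x, "species"))) cat(sprintf("Species: %s\n", attr(x, "species")))
  invisible(x)
}

pair_keys <- function(tf, tg) paste(tf, tg, sep = "\r")

#' Sample negative TF-target pairs
#'
#' Draws `n` distinct pairs uniformly without replacement from the admissible
#' set: TFs from `tf_ids` crossed with `gene_universe`, excluding self-pairs
#' and any pair present in `positives`.
#'
#' @param tf_ids Character vector of TF identifiers.
#' @param gene_universe Character vector of candidate partner genes.
#' @param positives A `pair_set` (or data frame with `tf_id`/`target_id`) of
#'   known positives to exclude.
#' @param n Number of negatives to draw.
#' @param seed Integer seed; draws are reproducible.
#' @return A `pair_set` of `n` pairs labeled 0 with source
#'   `"sampled_negative"`.
#' @export
#' @examples
#' pos <- pair_set("t1", "g1", 1)
#' sample_negative_pairs("t1", c("g1", "g2"), pos, 1, seed = 1)
sample_negative_pairs <- function(tf_ids, gene_universe, positives, n, seed) {
  tf_ids <- unique(as.character(tf_ids))
  gene_universe <- unique(as.character(gene_universe))
  if (!length(tf_ids) || !length(gene_universe)) fail("empty TF list or gene universe")
  if (is.null(positives)) {
    positives <- data.frame(tf_id = character(), target_id = character(),
                            stringsAsFactors = FALSE)
  }
  pos_key <- character()
  if (nrow(positives)) {
    pos_key <- unique(pair_keys(positives$tf_id, positives$target_id))
  }
  total <- length(tf_ids) * length(gene_universe)
  n_self <- sum(tf_ids %in% gene_universe)
  # positives that fall inside the TF x universe grid and are not self-pairs
  in_grid <- positives$tf_id %in% tf_ids & positives$target_id %in% gene_universe &
    positives$tf_id != positives$target_id
  n_pos_excl <- if (nrow(positives)) {
    length(unique(pair_keys(positives$tf_id[in_grid], positives$target_id[in_grid])))
  } else 0L
  admissible <- total - n_self - n_pos_excl
  if (n > admissible) {
    fail("requested %d negative pairs but only %d admissible pairs exist", n, admissible)
  }
  with_seed(seed, {
    if (total <= 2e6) {
      # exact enumeration of the admissible set
      idx <- expand.grid(t = seq_along(tf_ids), g = seq_along(gene_universe))
      tf <- tf_ids[idx$t]
      tg <- gene_universe[idx$g]
      ok_idx <- which(tf != tg & !(pair_keys(tf, tg) %in% pos_key))
      pick <- ok_idx[sample.int(length(ok_idx), n)]
      tf <- tf[pick]; tg <- tg[pick]
    } else {
      # rejection sampling with de-duplication: still uniform without
      # replacement over the admissible set
      seen <- character()
      tf <- character(); tg <- character()
      while (length(tf) < n) {
        m <- max(2L * (n - length(tf)), 1000L)
        ct <- tf_ids[sample.int(length(tf_ids), m, replace = TRUE)]
        cg <- gene_universe[sample.int(length(gene_universe), m, replace = TRUE)]
        key <- pair_keys(ct, cg)
        ok <- ct != cg & !(key %in% pos_key) & !(key %in% seen) & !duplicated(key)
        take <- which(ok)[seq_len(min(sum(ok), n - length(tf)))]
        tf <- c(tf, ct[take]); tg <- c(tg, cg[take])
        seen <- c(seen, key[take])
      }
    }
    pair_set(tf, tg, 0L, "sampled_negative")
  })
}

#' Transfer positive pairs to another species through homolog maps
#'
#' For each source positive pair, emits the cartesian product of the TF's
#' homologs and the target's homologs. Pairs with no homolog on either side
#' are dropped and logged; the expanded set is de-duplicated.
#'
#' @param positives A `pair_set` of label-1 pairs in the source species.
#' @param tf_map,gene_map Homolog maps: named lists mapping a source-species
#'   identifier to a character vector of target-species identifiers (see
#'   [homolog_map()]).
#' @return A `pair_set` labeled 1 with source `"homolog_mapped"`; the number of
#'   dropped source pairs is attached as attribute `n_dropped` and the dropped
#'   pairs themselves as attribute `dropped`.
#' @export
map_pairs_by_homology <- function(positives, tf_map, gene_map) {
  if (any(positives$label != 1, na.rm = TRUE) || anyNA(positives$label)) {
    fail("homology mapping expects positives only (all labels 1)")
  }
  out_tf <- vector("list", nrow(positives))
  out_tg <- vector("list", nrow(positives))
  dropped <- logical(nrow(positives))
  for (i in seq_len(nrow(positives))) {
    ht <- tf_map[[positives$tf_id[i]]]
    hg <- gene_map[[positives$target_id[i]]]
    if (is.null(ht) || !length(ht) || is.null(hg) || !length(hg)) {
      dropped[i] <- TRUE
      next
    }
    grid <- expand.grid(tf = ht, tg = hg, stringsAsFactors = FALSE)
    out_tf[[i]] <- grid$tf
    out_tg[[i]] <- grid$tg
  }
  if (any(dropped)) {
    log_msg("homology mapping dropped %d source pair(s) with no homolog", sum(dropped))
  }
  tf <- unlist(out_tf, use.names = FALSE)
  tg <- unlist(out_tg, use.names = FALSE)
  if (is.null(tf)) tf <- character()
  if (is.null(tg)) tg <- character()
  key <- pair_keys(tf, tg)
  keep <- !duplicated(key)
  res <- pair_set(tf[keep], tg[keep], 1L, "homolog_mapped")
  attr(res, "n_dropped") <- sum(dropped)
  attr(res, "dropped") <- positives[dropped, c("tf_id", "target_id")]
  res
}

#' Construct a homolog map
#'
#' @param source_ids Character vector of source-species identifiers.
#' @param target_ids Character vector (same length) of target-species
#'   identifiers; repeated source IDs accumulate multiple homologs.
#' @return A named list mapping each source ID to its homolog set. Empty
#'   target sets are never stored.
#' @export
homolog_map <- function(source_ids, target_ids) {
  source_ids <- as.character(source_ids)
  target_ids <- as.character(target_ids)
  if (length(source_ids) != length(target_ids)) fail("ID vectors must have equal length")
  if (any(!nzchar(source_ids)) || any(!nzchar(target_ids))) fail("empty identifier in homolog map")
  split(target_ids, factor(source_ids, levels = unique(source_ids)))
}

#' Read a two-column homolog map TSV
#' @param path Path to a TSV with columns `source_id`, `target_id` (header
#'   optional but recommended).
#' @return A homolog map (named list), as from [homolog_map()].
#' @export
read_homolog_map <- function(path) {
  df <- read_tsv_plain(path)
  if (ncol(df) < 2) fail("'%s': expected two columns (source_id, target_id)", path)
  homolog_map(df[[1]], df[[2]])
}

#' All ordered TF x pathway-gene pairs
#'
#' @param tf_ids Character vector of TFs (duplicate-free).
#' @param pathway_gene_ids Character vector of pathway genes (duplicate-free).
#' @return An unlabeled `pair_set` of `length(tf_ids) * length(pathway_gene_ids)`
#'   pairs with source `"cross_pair"`, ordered TF-major.
#' @export
#' @examples
#' nrow(cross_pairs(c("t1", "t2"), c("g1", "g2", "g3")))  # 6
cross_pairs <- function(tf_ids, pathway_gene_ids) {
  tf_ids <- as.character(tf_ids)
  pathway_gene_ids <- as.character(pathway_gene_ids)
  if (!length(tf_ids) || !length(pathway_gene_ids)) fail("both ID lists must be nonempty")
  if (anyDuplicated(tf_ids)) {
    fail("duplicate TF ID(s): %s", paste(unique(tf_ids[duplicated(tf_ids)]), collapse = ", "))
  }
  if (anyDuplicated(pathway_gene_ids)) {
    fail("duplicate pathway gene ID(s): %s",
         paste(unique(pathway_gene_ids[duplicated(pathway_gene_ids)]), collapse = ", "))
  }
  grid <- expand.grid(tg = pathway_gene_ids, tf = tf_ids,
                      stringsAsFactors = FALSE)  # tf-major order
  pair_set(grid$tf, grid$tg, NA_integer_, "cross_pair")
}

#' Build the pair feature matrix for a pair set
#'
#' Each retained pair becomes one row: the TF's expression vector over all `S`
#' compendium samples, followed by the target's (`2S` columns). Pairs whose TF
#' or target is absent from the compendium are dropped with a logged count.
#' The TF-block-then-target-block order is fixed: the CNN input reshape
#' ([pair_to_grid()]) depends on it.
#'
#' @param pairs A `pair_set`.
#' @param comp An `expr_compendium`.
#' @return A numeric matrix of class `pair_features`
#'   (`n_retained x 2S`) with attributes `pairs` (the retained `pair_set`),
#'   `labels` (aligned 0/1/NA vector) and `n_dropped`.
#' @export
build_feature_matrix <- function(pairs, comp) {
  stopifnot(inherits(comp, "expr_compendium"))
  if (ncol(comp$values) < 1) fail("compendium has no samples")
  tf_idx <- match(pairs$tf_id, rownames(comp$values))
  tg_idx <- match(pairs$target_id, rownames(comp$values))
  keep <- !is.na(tf_idx) & !is.na(tg_idx)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    log_msg("dropped %d pair(s) with genes absent from the compendium", n_dropped)
  }
  if (!any(keep)) fail("no pairs retained: none of the genes are in the compendium")
  x <- cbind(comp$values[tf_idx[keep], , drop = FALSE],
             comp$values[tg_idx[keep], , drop = FALSE])
  dimnames(x) <- list(NULL, c(paste0("tf_", colnames(comp$values)),
                              paste0("tg_", colnames(comp$values))))
  retained <- pairs[keep, , drop = FALSE]
  class(retained) <- c("pair_set", "data.frame")
  structure(x, class = c("pair_features", "matrix", "array"),
            pairs = retained, labels = retained$label, n_dropped = n_dropped)
}

#' @export
print.pair_features <- function(x, ...) {
  cat(sprintf("Pair feature matrix: %d pairs x %d features (2 x %d samples)\n",
              nrow(x), ncol(x), ncol(x) / 2))
  invisible(x)
}

#' Labels aligned with a pair feature matrix
#' @param x A `pair_features` matrix.
#' @return Integer 0/1/NA vector of length `nrow(x)`.
#' @export
feature_labels <- function(x) attr(x, "labels")

#' Stratified train/holdout split of a labeled pair set
#'
#' @param pairs A labeled `pair_set` with both classes present.
#' @param test_fraction Fraction reserved for the holdout test set
#'   (default 0.2).
#' @param seed Integer seed.
#' @return A list with `train` and `test` pair sets; disjoint, union equals
#'   the input, stratified by label.
#' @export
split_holdout <- function(pairs, test_fraction = 0.2, seed = 1) {
  if (anyNA(pairs$label)) fail("split_holdout needs a fully labeled pair set")
  tab <- table(pairs$label)
  if (length(tab) < 2) fail("both classes must be present")
  if (any(tab < 2)) fail("each class needs >= 2 members (got %s)",
                         paste(tab, collapse = ", "))
  with_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$label), function(ix) {
      sample(ix, round(test_fraction * length(ix)))
    }), use.names = FALSE)
  })
  test <- pairs[sort(test_idx), , drop = FALSE]
  train <- pairs[setdiff(seq_len(nrow(pairs)), test_idx), , drop = FALSE]
  class(test) <- class(train) <- c("pair_set", "data.frame")
  list(train = train, test = test)
}

#' Read / write pair lists as TSV
#'
#' `read_pair_set` expects columns `tf_id`, `target_id` and optionally
#' `label`; `write_pair_set` writes those columns plus `source` with a
#' provenance header.
#'
#' @param path File path.
#' @param species Optional species tag.
#' @return `read_pair_set`: a `pair_set`.
#' @export
read_pair_set <- function(path, species = NA_character_) {
  df <- read_tsv_plain(path)
  if (!all(c("tf_id", "target_id") %in% colnames(df))) {
    fail("'%s': expected columns tf_id, target_id", path)
  }
  lab <- if ("label" %in% colnames(df)) df$label else NA_integer_
  src <- if ("source" %in% colnames(df)) df$source else
    ifelse(is.na(rep_len(lab, nrow(df))), "cross_pair",
           ifelse(rep_len(lab, nrow(df)) == 1, "curated", "sampled_negative"))
  pair_set(df$tf_id, df$target_id, lab, src, species)
}

#' @rdname read_pair_set
#' @param pairs A `pair_set` to write.
#' @param header Optional named character vector of header comments.
#' @export
write_pair_set <- function(pairs, path, header = character()) {
  write_tsv_atomic(as.data.frame(pairs), path, header)
}
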