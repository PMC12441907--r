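test_that("pair sets enforce label and duplicate invariants", {
  expect_error(pair_set("t1", c("g1", "g2")), "lengths differ")
  expect_error(pair_set(c("t1", "t1"), c("g1", "g1"), 1), "duplicate pair")
  expect_error(pair_set(c("t1", "t1"), c("g1", "g1"), c(1, 0)), "both labels")
  expect_error(pair_set("t1", "g1", 2), "labels must be")
  ps <- pair_set(c("t1", "t2"), c("g1", "g1"), c(1, 0),
                 c("curated", "sampled_negative"))
  expect_s3_class(ps, "pair_set")
})

test_that("negative sampling draws only admissible pairs", {
  pos <- pair_set("t1", "g1", 1)
  neg <- sample_negative_pairs("t1", c("g1", "g2"), pos, 1, seed = 1)
  expect_identical(neg$tf_id, "t1")
  expect_identical(neg$target_id, "g2")  # the only admissible pair
  expect_identical(neg$label, 0L)
  expect_error(sample_negative_pairs("t1", c("g1", "g2"), pos, 2, seed = 1),
               "2.*1 admissible")
})

test_that("negative draws are disjoint from positives and duplicate-free across seeds", {
  tfs <- c("t1", "t2", "t3")
  universe <- c(sprintf("g%d", 1:8), "t1", "t2")  # TFs in the universe: self-pairs possible
  set.seed(99)
  pos <- pair_set(sample(tfs, 5, replace = TRUE), sprintf("g%d", 1:5), 1)
  # independent enumeration of the admissible set
  grid <- expand.grid(tf = tfs, tg = universe, stringsAsFactors = FALSE)
  key <- function(a, b) paste(a, b, sep = "|")
  admissible <- key(grid$tf, grid$tg)[grid$tf != grid$tg &
    !(key(grid$tf, grid$tg) %in% key(pos$tf_id, pos$target_id))]
  for (seed in 1:500) {
    neg <- sample_negative_pairs(tfs, universe, pos, 20, seed = seed)
    k <- key(neg$tf_id, neg$target_id)
    expect_equal(anyDuplicated(k), 0L)
    expect_true(all(k %in% admissible))
  }
  # reproducibility
  expect_identical(sample_negative_pairs(tfs, universe, pos, 10, seed = 7),
                   sample_negative_pairs(tfs, universe, pos, 10, seed = 7))
})

test_that("negative sampling on a large universe avoids full enumeration", {
  tfs <- sprintf("T%04d", 1:2100)
  universe <- sprintf("G%04d", 1:1200)  # 2.52e6 candidate pairs
  pos <- pair_set(tfs[1:50], universe[1:50], 1)
  neg <- sample_negative_pairs(tfs, universe, pos, 500, seed = 3)
  expect_equal(nrow(neg), 500)
  k <- paste(neg$tf_id, neg$target_id)
  expect_equal(anyDuplicated(k), 0L)
  expect_false(any(k %in% paste(pos$tf_id, pos$target_id)))
})

test_that("homology mapping expands by cartesian product and logs drops", {
  pos <- pair_set("A", "B", 1)
  tf_map <- homolog_map(c("A", "A"), c("a1", "a2"))
  gene_map <- homolog_map("B", "b1")
  out <- map_pairs_by_homology(pos, tf_map, gene_map)
  expect_setequal(paste(out$tf_id, out$target_id),
                  c("a1 b1", "a2 b1"))
  expect_true(all(out$label == 1L))
  expect_true(all(out$source == "homolog_mapped"))

  # missing homolog: dropped, not fatal
  out2 <- suppressMessages(
    map_pairs_by_homology(pos, homolog_map(character(), character()), gene_map))
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "n_dropped"), 1)

  neg <- pair_set("A", "B", 0)
  expect_error(map_pairs_by_homology(neg, tf_map, gene_map), "positives only")
})

test_that("homology expansion size matches direct enumeration on random fan-outs", {
  set.seed(42)
  src_tfs <- sprintf("TF%02d", 1:10)
  src_genes <- sprintf("GN%02d", 1:40)
  pos <- pair_set(sample(src_tfs, 100, replace = TRUE), sample(src_genes, 100, replace = TRUE), NA)
  pos <- pos[!duplicated(paste(pos$tf_id, pos$target_id)), ]
  pos$label <- 1L
  class(pos) <- c("pair_set", "data.frame")
  fan <- function(ids, tag) {
    out <- lapply(ids, function(id) sprintf("%s_%s%d", id, tag, seq_len(sample(1:3, 1))))
    stats::setNames(out, ids)
  }
  tf_map <- fan(src_tfs, "t")
  gene_map <- fan(src_genes, "g")
  out <- map_pairs_by_homology(pos, tf_map, gene_map)
  # independent enumeration
  keys <- character()
  for (i in seq_len(nrow(pos))) {
    for (a in tf_map[[pos$tf_id[i]]]) {
      for (b in gene_map[[pos$target_id[i]]]) keys <- c(keys, paste(a, b))
    }
  }
  expect_equal(nrow(out), length(unique(keys)))
  expect_setequal(paste(out$tf_id, out$target_id), unique(keys))
  # mapping never invents IDs outside the map codomains
  expect_true(all(out$tf_id %in% unlist(tf_map)))
  expect_true(all(out$target_id %in% unlist(gene_map)))
})

test_that("cross pairing yields exactly |TFs| x |genes| ordered pairs", {
  # the pathway-scan arithmetic: 1,415 TFs x 20 pathway genes and
  # 1,717 TFs x 25 genes
  cp1 <- cross_pairs(sprintf("TF%04d", 1:1415), sprintf("LBP%02d", 1:20))
  expect_equal(nrow(cp1), 28300)
  cp2 <- cross_pairs(sprintf("TF%04d", 1:1717), sprintf("LBP%02d", 1:25))
  expect_equal(nrow(cp2), 42925)
  expect_true(all(is.na(cp1$label)))
  expect_true(all(cp1$source == "cross_pair"))
  expect_equal(nrow(cross_pairs("t", "g")), 1)
  expect_error(cross_pairs(c("t", "t"), "g"), "duplicate TF")
  expect_error(cross_pairs("t", c("g", "g")), "duplicate pathway")
  expect_error(cross_pairs(character(), "g"), "nonempty")
})

test_that("feature rows concatenate TF block then target block", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("tf", "tg"), c("a", "b", "c")))
  comp <- expression_compendium(m)
  x <- build_feature_matrix(pair_set("tf", "tg", 1), comp)
  expect_equal(unname(x[1, ]), c(1, 2, 3, 4, 5, 6))
  expect_equal(ncol(x), 2 * ncol(m))
})

test_that("pairs with genes missing from the compendium are dropped and logged", {
  m <- tiny_count_matrix(5, 3)
  comp <- expression_compendium(m)
  pairs <- pair_set(c("g001", "g002", "nope"), c("g003", "ghost", "g004"),
                    c(1, 1, 0), c("curated", "curated", "sampled_negative"))
  expect_message(x <- build_feature_matrix(pairs, comp), "dropped 2")
  expect_equal(nrow(x), 1)
  expect_equal(attr(x, "n_dropped"), 2)
  expect_equal(feature_labels(x), 1L)
  all_missing <- pair_set("zz", "ww", 1)
  expect_error(suppressMessages(build_feature_matrix(all_missing, comp)),
               "no pairs retained")
})

test_that("feature matrix width is always twice the sample count", {
  for (S in c(1, 7, 30)) {
    m <- tiny_count_matrix(10, S, seed = S)
    comp <- expression_compendium(m)
    pairs <- pair_set(c("g001", "g002"), c("g003", "g004"), c(1, 0),
                      c("curated", "sampled_negative"))
    expect_equal(ncol(build_feature_matrix(pairs, comp)), 2 * S)
  }
})

test_that("holdout split is stratified, disjoint, and seed-reproducible", {
  pairs <- pair_set(sprintf("t%d", 1:20), sprintf("g%d", 1:20),
                    rep(c(1, 0), each = 10),
                    rep(c("curated", "sampled_negative"), each = 10))
  sp <- split_holdout(pairs, 0.2, seed = 4)
  expect_equal(sum(sp$test$label == 1), 2)
  expect_equal(sum(sp$test$label == 0), 2)
  expect_equal(nrow(sp$train) + nrow(sp$test), 20)
  k <- function(p) paste(p$tf_id, p$target_id)
  expect_length(intersect(k(sp$train), k(sp$test)), 0)
  sp2 <- split_holdout(pairs, 0.2, seed = 4)
  expect_identical(k(sp$test), k(sp2$test))

  one_class <- pair_set("t", "g", 1)
  expect_error(split_holdout(one_class, 0.2, 1), "both classes")
})

test_that("holdout sizes and class balance hold across random set sizes", {
  set.seed(10)
  for (i in 1:200) {
    n_pos <- sample(5:40, 1)
    n_neg <- sample(5:40, 1)
    pairs <- pair_set(sprintf("t%d", seq_len(n_pos + n_neg)),
                      sprintf("g%d", seq_len(n_pos + n_neg)),
                      c(rep(1, n_pos), rep(0, n_neg)),
                      c(rep("curated", n_pos), rep("sampled_negative", n_neg)))
    sp <- split_holdout(pairs, 0.2, seed = i)
    expect_lte(abs(nrow(sp$test) - round(0.2 * (n_pos + n_neg))), 1)
    expect_equal(sum(sp$test$label == 1), round(0.2 * n_pos))
    expect_equal(sum(sp$test$label == 0), round(0.2 * n_neg))
  }
})

test_that("pair sets round trip through TSV", {
  pairs <- pair_set(c("t1", "t2"), c("g1", "g2"), c(1, 0),
                    c("curated", "sampled_negative"), species = "synthetic")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_set(pairs, path, header = c(seed = "1"))
  expect_true(startsWith(readLines(path, n = 1), "# version:"))
  back <- read_pair_set(path)
  expect_equal(back$tf_id, pairs$tf_id)
  expect_equal(back$label, pairs$label)
})
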