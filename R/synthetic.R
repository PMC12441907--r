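#' Specification for a synthetic expression compendium with planted regulation
#'
#' The generator emulates the statistical structure supervised TF-target
#' classification assumes: regulated targets co-express with their TF
#' (through a possibly nonlinear, noisy coupling), everything else is
#' independent. Defaults are the conditions used throughout the package's
#' signal-recovery checks: 200 samples, coupling coefficient 2, noise SD 0.5,
#' 1,000 positive pairs.
#'
#' @param n_genes Total genes (TFs included).
#' @param n_tfs Number of TFs (the first `n_tfs` genes).
#' @param n_samples Number of samples.
#' @param n_positive_pairs Number of planted TF-target pairs; each regulated
#'   target has exactly one TF regulator, so this must not exceed
#'   `n_genes - n_tfs`.
#' @param signal Coupling coefficient `beta >= 0`; per-pair couplings are
#'   jittered +/-50\% with random sign so no single constant identifies
#'   positives.
#' @param noise_sd Gaussian noise SD on regulated targets (> 0).
#' @param nonlinearity `"linear"`, `"quadratic"` or `"threshold"` coupling.
#' @param count_mode If `TRUE`, latent expression is passed through an
#'   exponential link into overdispersed negative-binomial counts with
#'   sample-specific library-size factors spanning at least 4-fold (for
#'   exercising TMM normalization).
#' @param seed Integer seed; generation is bitwise reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 1200L, n_tfs = 100L, n_samples = 200L,
                           n_positive_pairs = 1000L, signal = 2,
                           noise_sd = 0.5,
                           nonlinearity = c("linear", "quadratic", "threshold"),
                           count_mode = FALSE, seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_tfs > n_genes) fail("n_tfs (%d) exceeds n_genes (%d)", n_tfs, n_genes)
  if (n_positive_pairs > n_genes - n_tfs) {
    fail("n_positive_pairs (%d) exceeds the number of non-TF genes (%d): each regulated target has one TF regulator",
         n_positive_pairs, n_genes - n_tfs)
  }
  if (signal < 0) fail("signal must be >= 0")
  if (noise_sd <= 0) fail("noise_sd must be > 0")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_samples = as.integer(n_samples),
                 n_positive_pairs = as.integer(n_positive_pairs),
                 signal = signal, noise_sd = noise_sd,
                 nonlinearity = nonlinearity, count_mode = isTRUE(count_mode),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

apply_coupling <- function(u, nonlinearity) {
  switch(nonlinearity,
         linear = u,
         quadratic = u^2,
         threshold = ifelse(u > 0, 1, -1))
}

# standardize every gene row to mean 0, SD 1 so that marginal distributions
# carry no class signal: only the TF-target dependence separates positives
# from negatives
standardize_rows <- function(L) {
  mu <- rowMeans(L)
  sd_ <- sqrt(rowSums((L - mu)^2) / (ncol(L) - 1))
  (L - mu) / sd_
}

# exponential link into overdispersed counts with >=4-fold library spread
latent_to_counts <- function(L, base_mean = 30, dispersion = 10) {
  S <- ncol(L)
  # library-size factors on a fixed 5-fold geometric grid, randomly assigned
  # to samples, so the spread is guaranteed regardless of S
  libf <- sample(exp(seq(log(0.5), log(2.5), length.out = S)))
  mu <- sweep(exp(0.5 * L) * base_mean, 2, libf, "*")
  cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
                nrow(L), S)
  dimnames(cnt) <- dimnames(L)
  cnt
}

#' Generate a synthetic dataset from a spec
#'
#' TF expression is standard-normal per sample; each planted positive target
#' equals `f(beta * TF) + N(0, noise_sd)` with the per-pair jittered
#' coupling; non-target genes are independent noise. In count mode the latent
#' matrix is emitted as overdispersed counts (see [synthetic_spec()]).
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset` with `compendium`
#'   ([expression_compendium()]), `positives` (a `pair_set`; also the full
#'   ground truth — all other pairs are negative), `tf_ids`, and `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_genes = 60, n_tfs = 10,
#'                                       n_samples = 30, n_positive_pairs = 20))
#' dim(ds$compendium)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    g_ids <- sprintf("G%05d", seq_len(spec$n_genes))
    tf_ids <- g_ids[seq_len(spec$n_tfs)]
    S <- spec$n_samples
    L <- matrix(stats::rnorm(spec$n_genes * S), spec$n_genes, S,
                dimnames = list(g_ids, sprintf("S%04d", seq_len(S))))
    non_tf <- g_ids[-seq_len(spec$n_tfs)]
    targets <- sample(non_tf, spec$n_positive_pairs)
    tfs <- sample(tf_ids, spec$n_positive_pairs, replace = TRUE)
    beta <- spec$signal * stats::runif(spec$n_positive_pairs, 0.5, 1.5) *
      sample(c(-1, 1), spec$n_positive_pairs, replace = TRUE)
    U <- L[tfs, , drop = FALSE] * beta
    L[targets, ] <- apply_coupling(U, spec$nonlinearity) +
      matrix(stats::rnorm(spec$n_positive_pairs * S, sd = spec$noise_sd),
             spec$n_positive_pairs, S)
    L <- standardize_rows(L)
    vals <- if (spec$count_mode) latent_to_counts(L) else L - min(L)
    comp <- expression_compendium(vals, normalized = !spec$count_mode)
    positives <- pair_set(tfs, targets, 1L, "curated", "synthetic")
    attr(positives, "beta") <- beta
    structure(list(compendium = comp, positives = positives, tf_ids = tf_ids,
                   spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d genes (%d TFs) x %d samples, %d planted positives (signal %.2g, noise SD %.2g, %s%s)\n",
              x$spec$n_genes, x$spec$n_tfs, x$spec$n_samples,
              nrow(x$positives), x$spec$signal, x$spec$noise_sd,
              x$spec$nonlinearity, if (x$spec$count_mode) ", counts" else ""))
  invisible(x)
}

#' Generate a homolog-linked two-species dataset
#'
#' The source species comes from [generate_dataset()]. Target-species genes
#' are `fanout` homolog copies of each source gene: TF copies share the
#' source TF's latent signal attenuated by `divergence`
#' (`sqrt(1 - d^2) * z + d * noise`), and regulated-target copies follow the
#' same coupling with the coefficient perturbed by `divergence`. Every
#' homolog-mapped pair is therefore a genuine (noisier) positive, and the
#' regulatory logic degrades smoothly as `divergence` grows. Homolog maps are
#' emitted separately for TFs and non-TFs, and the target positives are
#' produced by [map_pairs_by_homology()] itself.
#'
#' @param spec A [synthetic_spec()] for the source species.
#' @param divergence Regulatory divergence level in `[0, 1]`; 0 reproduces
#'   the source process up to sample resampling.
#' @param fanout Homolog multiplicity per source gene (>= 1).
#' @return A list with `source` and `target` (`synthetic_dataset`s),
#'   `tf_map` and `gene_map` (homolog maps), `divergence`, `fanout`.
#' @export
generate_species_pair <- function(spec, divergence = 0.1, fanout = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (fanout < 1) fail("fanout must be >= 1")
  if (divergence < 0 || divergence > 1) fail("divergence must be in [0, 1]")
  source <- generate_dataset(spec)
  fanout <- as.integer(fanout)
  d <- divergence
  with_seed(derive_seed(spec$seed, "species2"), {
    S <- spec$n_samples
    g_ids <- gene_ids(source$compendium)
    tf_src <- source$tf_ids
    copies <- function(id) sprintf("%s_h%d", id, seq_len(fanout))
    tf_map <- stats::setNames(lapply(tf_src, copies), tf_src)
    non_tf <- setdiff(g_ids, tf_src)
    gene_map <- stats::setNames(lapply(non_tf, copies), non_tf)
    # fresh shared latent TF signals for the new species' samples
    Z2 <- matrix(stats::rnorm(length(tf_src) * S), length(tf_src), S,
                 dimnames = list(tf_src, NULL))
    t_ids <- unlist(lapply(g_ids, copies), use.names = FALSE)
    L <- matrix(stats::rnorm(length(t_ids) * S), length(t_ids), S,
                dimnames = list(t_ids, sprintf("S%04d", seq_len(S))))
    # TF copies: divergence-attenuated shares of the latent signal
    for (tf in tf_src) {
      for (cp in tf_map[[tf]]) {
        L[cp, ] <- sqrt(1 - d^2) * Z2[tf, ] + d * stats::rnorm(S)
      }
    }
    # regulated-target copies follow the source coupling, perturbed
    beta <- attr(source$positives, "beta")
    for (i in seq_len(nrow(source$positives))) {
      tf <- source$positives$tf_id[i]
      for (cp in gene_map[[source$positives$target_id[i]]]) {
        b2 <- beta[i] * (1 + d * stats::rnorm(1))
        L[cp, ] <- apply_coupling(b2 * Z2[tf, ], spec$nonlinearity) +
          stats::rnorm(S, sd = spec$noise_sd * (1 + d))
      }
    }
    L <- standardize_rows(L)
    vals <- if (spec$count_mode) latent_to_counts(L) else L - min(L)
    comp2 <- expression_compendium(vals, normalized = !spec$count_mode)
    positives2 <- map_pairs_by_homology(source$positives, tf_map, gene_map)
    spec2 <- spec
    spec2$n_genes <- length(t_ids)
    spec2$n_tfs <- length(tf_src) * fanout
    target <- structure(list(compendium = comp2, positives = positives2,
                             tf_ids = unlist(tf_map, use.names = FALSE),
                             spec = spec2),
                        class = "synthetic_dataset")
    list(source = source, target = target, tf_map = tf_map,
         gene_map = gene_map, divergence = divergence, fanout = fanout)
  })
}

#' Write a synthetic dataset in the pipeline's own TSV formats
#'
#' Emits `matrix.tsv` (expression matrix), `positives.tsv` (pair list),
#' and `tfs.txt` (one TF ID per line) under `dir`, so fixtures double as
#' format documentation.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @param header Optional named character vector of provenance header fields.
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(ds, dir, header = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- c(header, seed = as.character(ds$spec$seed),
           config = config_hash(ds$spec))
  write_expression_matrix(ds$compendium, file.path(dir, "matrix.tsv"),
                          header = hdr)
  write_pair_set(ds$positives, file.path(dir, "positives.tsv"), header = hdr)
  writeLines(ds$tf_ids, file.path(dir, "tfs.txt"))
  invisible(dir)
}
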