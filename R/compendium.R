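#' Expression compendium container
#'
#' A gene-by-sample matrix of non-negative expression values (raw counts or
#' normalized expression) with unique gene and sample identifiers. This is the
#' substrate every downstream stage works from: pair featurization concatenates
#' two of its rows, and TMM normalization rescales its columns.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of gene identifiers (defaults to rownames).
#' @param sample_ids Character vector of sample identifiers (defaults to
#'   colnames).
#' @param normalized Logical; `TRUE` once values are normalized expression
#'   rather than raw counts.
#' @return An object of class `expr_compendium`: a list with elements
#'   `values` (the matrix, dimnames set to the IDs) and `normalized`.
#' @export
#' @examples
#' m <- matrix(rpois(6, 10), 3, 2,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' comp <- expression_compendium(m)
#' dim(comp)
expression_compendium <- function(values, gene_ids = rownames(values),
                                  sample_ids = colnames(values),
                                  normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    fail("'values' must be a numeric matrix")
  }
  if (is.null(gene_ids) || is.null(sample_ids)) {
    fail("gene and sample identifiers are required (rownames/colnames or explicit)")
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    fail("identifier lengths (%d genes, %d samples) do not match matrix shape %d x %d",
         length(gene_ids), length(sample_ids), nrow(values), ncol(values))
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) fail("duplicate gene ID(s): %s", paste(dup_g, collapse = ", "))
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) fail("duplicate sample ID(s): %s", paste(dup_s, collapse = ", "))
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    fail("non-finite value at gene '%s', sample '%s'",
         gene_ids[bad[1]], sample_ids[bad[2]])
  }
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    fail("negative value at gene '%s', sample '%s'",
         gene_ids[bad[1]], sample_ids[bad[2]])
  }
  storage.mode(values) <- "double"
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, normalized = isTRUE(normalized)),
            class = "expr_compendium")
}

#' @export
dim.expr_compendium <- function(x) dim(x$values)

#' @export
print.expr_compendium <- function(x, ...) {
  cat(sprintf("Expression compendium: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Gene and sample identifiers of a compendium
#' @param comp An `expr_compendium`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(comp) rownames(comp$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(comp) colnames(comp$values)

#' Read an expression matrix from a delimited text file
#'
#' Expects a header row of sample IDs and a first column of gene IDs. Any cell
#' that is not a finite non-negative number is a hard error naming the gene and
#' sample, as are duplicated identifiers. Lines starting with `#` are skipped.
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter (default tab).
#' @return An [expression_compendium()].
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) fail("file not found: '%s'", path)
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) fail("'%s': expected a gene-ID column plus >=1 sample column", path)
  genes <- raw[[1]]
  samples <- colnames(raw)[-1]
  dup_g <- unique(genes[duplicated(genes)])
  if (length(dup_g)) fail("'%s': duplicate gene ID(s): %s", path, paste(dup_g, collapse = ", "))
  dup_s <- unique(samples[duplicated(samples)])
  if (length(dup_s)) fail("'%s': duplicate sample ID(s): %s", path, paste(dup_s, collapse = ", "))
  vals <- suppressWarnings(
    vapply(raw[-1], function(col) as.numeric(col), numeric(nrow(raw)))
  )
  vals <- matrix(vals, nrow = length(genes))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    fail("'%s': non-numeric value '%s' at gene '%s', sample '%s'",
         path, raw[[bad[1, 2] + 1]][bad[1, 1]], genes[bad[1, 1]], samples[bad[1, 2]])
  }
  if (any(vals < 0)) {
    b <- which(vals < 0, arr.ind = TRUE)[1, ]
    fail("'%s': negative value at gene '%s', sample '%s'",
         path, genes[b[1]], samples[b[2]])
  }
  expression_compendium(vals, genes, samples)
}

#' Write an expression matrix to a delimited text file
#'
#' @param comp An `expr_compendium`.
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @param header Optional named character vector written as `# key: value`
#'   comment lines.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(comp, path, delimiter = "\t",
                                    header = character()) {
  stopifnot(inherits(comp, "expr_compendium"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(header)) {
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
  }
  writeLines(paste(c("gene_id", colnames(comp$values)), collapse = delimiter), con)
  body <- cbind(rownames(comp$values),
                apply(comp$values, 2, function(col) as.character(col)))
  utils::write.table(body, con, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' TMM normalization of a raw count compendium
#'
#' Computes per-sample scaling factors by the weighted trimmed mean of M-values
#' method. A reference sample is chosen as the sample whose upper quartile of
#' library-size-scaled nonzero counts is closest to the mean upper quartile.
#' For each sample, genes with a zero count in either the sample or the
#' reference are excluded; `M` is the log2 ratio of library-size-scaled counts
#' and `A` the mean log2 abundance. The top and bottom `logratio_trim` fraction
#' of M and `abs_expr_trim` fraction of A are trimmed (ranks tie-broken by a
#' stable sort on gene ID), and the factor is `2^` the precision-weighted mean
#' of the surviving M values with weights
#' `1 / ((N_k - y_gk)/(N_k y_gk) + (N_r - y_gr)/(N_r y_gr))`.
#' Factors are rescaled to geometric mean 1, and the normalized matrix is
#' `counts / (library_size * factor) * mean(library_size)` so magnitudes stay
#' on the counts scale.
#'
#' @param comp An `expr_compendium` of raw counts with at least two samples.
#' @param logratio_trim Fraction of M values trimmed from each tail
#'   (default 0.3).
#' @param abs_expr_trim Fraction of A values trimmed from each tail
#'   (default 0.05).
#' @return A list with `compendium` (normalized [expression_compendium()]) and
#'   `factors`, an object of class `tmm_factors`: a data frame
#'   `(sample_id, lib_size, factor)` with attributes `reference_sample_id`.
#' @export
#' @examples
#' m <- matrix(rpois(200, 20), 50, 4,
#'             dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:4)))
#' res <- tmm_normalize(expression_compendium(m))
#' res$factors
tmm_normalize <- function(comp, logratio_trim = 0.3, abs_expr_trim = 0.05) {
  stopifnot(inherits(comp, "expr_compendium"))
  y <- comp$values
  if (ncol(y) < 2) fail("TMM needs at least 2 samples, got %d", ncol(y))
  if (logratio_trim < 0 || logratio_trim >= 0.5) {
    fail("logratio_trim must be in [0, 0.5), got %g", logratio_trim)
  }
  if (abs_expr_trim < 0 || abs_expr_trim >= 0.5) {
    fail("abs_expr_trim must be in [0, 0.5), got %g", abs_expr_trim)
  }
  lib <- colSums(y)
  if (any(lib == 0)) {
    fail("sample(s) with all-zero counts: %s",
         paste(colnames(y)[lib == 0], collapse = ", "))
  }
  # reference: upper quartile of library-size-scaled nonzero counts closest to
  # the mean upper quartile
  uq <- vapply(seq_len(ncol(y)), function(k) {
    nz <- y[y[, k] > 0, k]
    stats::quantile(nz / lib[k], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  gid <- rownames(y)
  f <- vapply(seq_len(ncol(y)), function(k) {
    tmm_pair_factor(y[, k], y[, ref], lib[k], lib[ref], gid,
                    logratio_trim, abs_expr_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  eff <- lib * f
  norm <- sweep(y, 2, eff, "/") * mean(lib)
  factors <- data.frame(sample_id = colnames(y), lib_size = lib, factor = f,
                        row.names = NULL, stringsAsFactors = FALSE)
  attr(factors, "reference_sample_id") <- colnames(y)[ref]
  class(factors) <- c("tmm_factors", "data.frame")
  list(
    compendium = expression_compendium(norm, rownames(y), colnames(y),
                                       normalized = TRUE),
    factors = factors
  )
}

# single-sample TMM factor against a reference library (rank-based trimming,
# ties broken by stable sort on gene ID)
tmm_pair_factor <- function(yk, yr, nk, nr, gid, logratio_trim, abs_expr_trim) {
  use <- yk > 0 & yr > 0
  yk <- yk[use]; yr <- yr[use]; gid <- gid[use]
  if (!length(yk)) {
    warning("no genes with nonzero counts in both sample and reference; factor set to 1")
    return(1)
  }
  m <- log2((yk / nk) / (yr / nr))
  a <- 0.5 * log2((yk / nk) * (yr / nr))
  w <- 1 / ((nk - yk) / (nk * yk) + (nr - yr) / (nr * yr))
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abs_expr_trim) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- integer(n); rm_[order(m, gid)] <- seq_len(n)
  ra_ <- integer(n); ra_[order(a, gid)] <- seq_len(n)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  if (!any(keep)) {
    warning("all genes trimmed; factor set to 1")
    return(1)
  }
  2^(sum(w[keep] * m[keep]) / sum(w[keep]))
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat(sprintf("TMM normalization factors (reference sample: %s)\n",
              attr(x, "reference_sample_id")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Write TMM factors as a two-column TSV
#' @param factors A `tmm_factors` object.
#' @param path Output path.
#' @param header Optional named character vector of header comments.
#' @return Invisibly, `path`.
#' @export
write_tmm_factors <- function(factors, path, header = character()) {
  write_tsv_atomic(factors[, c("sample_id", "factor")], path,
                   c(header, reference = attr(factors, "reference_sample_id")))
}
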