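#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the previous
#' RNG state, so seeded package internals never perturb the caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a global seed
#'
#' A single run seed fans out to per-stage seeds through an FNV-1a hash of the
#' stage label, so each pipeline stage is independently reproducible. Results
#' stay below 2^31.
#'
#' @param seed Integer global seed.
#' @param label Character stage label (e.g. "negatives", "encoder").
#' @param index Optional integer (e.g. replicate number) mixed into the hash.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "encoder")
#' derive_seed(1, "encoder", 2)
derive_seed <- function(seed, label, index = 0L) {
  h <- fnv1a32(paste0(label, ":", index))
  as.integer((abs(as.numeric(seed)) + h) %% (2^31 - 2) + 1)
}

# 32-bit FNV-1a hash of a string, returned as a double in [0, 2^32).
fnv1a32 <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    h <- bitwXor32(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  h
}

# xor for doubles holding 32-bit unsigned values
bitwXor32 <- function(a, b) {
  hi_a <- a %/% 2^31
  lo_a <- a %% 2^31
  res_lo <- bitwXor(as.integer(lo_a), as.integer(b %% 2^31))
  hi_b <- b %/% 2^31
  (bitwXor(as.integer(hi_a), as.integer(hi_b)) * 2^31) + (res_lo %% 2^31)
}

#' @keywords internal
config_hash <- function(x) {
  h <- fnv1a32(paste(deparse(x), collapse = ""))
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# stop() with sprintf formatting and no call in the condition
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# informational logging to stderr
log_msg <- function(fmt, ...) message(sprintf(fmt, ...))

#' Write a table atomically with a provenance header
#'
#' Writes `df` as TSV to a temporary file in the destination directory and
#' renames it into place, prefixing `# key: value` header comment lines
#' (tool version, seed, config hash) so outputs are self-describing.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param header Named character vector of header fields (may be empty).
#' @return Invisibly, `path`.
#' @keywords internal
write_tsv_atomic <- function(df, path, header = character()) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wt")
  ok <- FALSE
  tryCatch({
    header <- c(version = as.character(utils::packageVersion("grnlearn")), header)
    writeLines(sprintf("# %s: %s", names(header), unname(header)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    fail("could not move temporary file into place at '%s'", path)
  }
  invisible(path)
}

# read a TSV written by write_tsv_atomic (comment lines skipped)
read_tsv_plain <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
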