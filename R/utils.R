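#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map_chr map2 imap
NULL

# quiet R CMD check notes for NSE column names
utils::globalVariables(c(
  ".", "genome", "genome_a", "genome_b", "gene", "gene_id", "family",
  "category", "value", "x", "sample_id", "pan_size", "core_size",
  "contig", "start", "end", "strand", "rank", "count", "k", "genomovar",
  "declared_name", "verdict", "branch", "gains", "losses", "identity_percent",
  "coverage", "evalue", "score", "curve", "term", "estimate", "n_genomes",
  "median_size", "kmer", "i", "j", "n_shared", "seq_a", "seq_b", "frag_idx",
  "offset", "diag_pos", "pct", "component", "gene_count"
))

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
}

# Draw n sub-seeds (31-bit) from a master seed without disturbing the caller's
# RNG stream more than once.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  as.list(s)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

`%||%` <- rlang::`%||%`
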