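# Karlin-Altschul-style constants for gapped BLOSUM62 (gap open 11, extend
# 1) used to turn local-alignment scores into a database-size-corrected
# significance estimate. Calibrated against shuffled decoy proteomes in the
# test-suite: decoys score no acceptable hits at the default cutoffs.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Search a proteome with a query protein
#'
#' Local pairwise alignment (BLOSUM62) of the query against every protein
#' passing a shared-k-mer prefilter. Significance is an extreme-value
#' estimate E = K m n exp(-lambda S) with n the total residue count of the
#' proteome. Hits must reach `min_identity` over the aligned region,
#' `min_coverage` of the query, and `max_significance`.
#'
#' @param query An `AAString`/character protein sequence.
#' @param proteome A named `AAStringSet` (or `genome_record`).
#' @param min_identity Identity fraction over the aligned region.
#' @param min_coverage Fraction of the query that must align.
#' @param max_significance E-value-style acceptance threshold.
#' @param kmer,min_shared Prefilter word size and required shared words.
#' @return Tibble of accepted hits sorted by score: gene, identity_percent,
#'   coverage, score, evalue.
#' @export
protein_search <- function(query, proteome, min_identity = 0.5,
                           min_coverage = 0.7, max_significance = 1e-5,
                           kmer = 4, min_shared = 2) {
  if (inherits(proteome, "genome_record")) proteome <- proteome$proteins
  q <- as.character(query)
  assert_that(nchar(q) > 0, "empty query")
  db <- as.character(proteome)
  m <- nchar(q)
  n_db <- sum(nchar(db))
  qk <- unique(substring(q, 1:(m - kmer + 1), kmer:m))
  shared <- vapply(db, function(s) {
    L <- nchar(s)
    if (L < kmer) return(0L)
    sum(qk %in% substring(s, 1:(L - kmer + 1), kmer:L))
  }, integer(1))
  cand <- which(shared >= min_shared)
  if (!length(cand)) {
    return(tibble(gene = character(), identity_percent = numeric(),
                  coverage = numeric(), score = numeric(), evalue = numeric()))
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(rep(q, length(cand))),
    Biostrings::AAStringSet(db[cand]),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  sc <- Biostrings::score(aln)
  ident <- Biostrings::nmatch(aln) / Biostrings::nchar(aln)
  qspan <- Biostrings::end(Biostrings::pattern(aln)) -
    Biostrings::start(Biostrings::pattern(aln)) + 1
  cover <- qspan / m
  ev <- KA_K * m * n_db * exp(-KA_LAMBDA * sc)
  ok <- ident >= min_identity & cover >= min_coverage & ev <= max_significance
  tibble(gene = names(proteome)[cand][ok],
         identity_percent = 100 * ident[ok],
         coverage = cover[ok], score = sc[ok], evalue = ev[ok]) |>
    arrange(desc(score))
}

#' Genes flanking an anchor gene
#'
#' Returns up to `flank` genes on each side of the anchor in genomic order
#' (per contig, ordered by start coordinate), with strands; truncation at a
#' contig end is flagged.
#'
#' @param genome A `genome_record`.
#' @param anchor Anchor gene id.
#' @param flank Number of genes on each side (default 20).
#' @return Tibble of the neighborhood (gene_id, contig, start, end, strand,
#'   offset relative to anchor) with attributes `truncated_left`/`_right`.
#' @export
neighborhood <- function(genome, anchor, flank = 20) {
  stopifnot(inherits(genome, "genome_record"))
  g <- genome$genes |> arrange(contig, start)
  hit <- which(g$gene_id == anchor)
  if (!length(hit)) abort(sprintf("anchor gene '%s' not found in %s",
                                  anchor, genome$id))
  ct <- g$contig[hit]
  on_ct <- which(g$contig == ct)
  pos <- match(hit, on_ct)
  lo <- max(1, pos - flank); hi <- min(length(on_ct), pos + flank)
  out <- g[on_ct[lo:hi], ] |> mutate(offset = (lo:hi) - pos)
  structure(out,
            truncated_left = (pos - lo) < flank,
            truncated_right = (hi - pos) < flank)
}

#' Presence of an ordered multi-gene cluster in a genome
#'
#' Searches each query protein with [protein_search()] and checks whether
#' all hits lie on one contig with at most `max_gap` intervening non-query
#' genes between consecutive members. Gene order within the cluster is
#' reported (`order_conserved`) but not required for completeness.
#' Status: `complete` (all genes, contiguous), `partial` (some genes, or
#' all genes but scattered), `absent` (none).
#'
#' @param genome A `genome_record`.
#' @param queries Named, ordered `AAStringSet` of query proteins (>= 2).
#' @param max_gap Maximum intervening genes between consecutive members.
#' @param ... Passed to [protein_search()].
#' @return One-row tibble: genome, status, n_found, found, missing, contig,
#'   max_intervening, order_conserved.
#' @export
cluster_presence <- function(genome, queries, max_gap = 2, ...) {
  stopifnot(inherits(genome, "genome_record"))
  assert_that(length(queries) >= 2, "need at least 2 query genes")
  hits <- lapply(seq_along(queries), function(i)
    protein_search(queries[[i]], genome, ...))
  best <- vapply(hits, function(h)
    if (nrow(h)) h$gene[1] else NA_character_, character(1))
  names(best) <- names(queries)
  found <- names(best)[!is.na(best)]
  missing <- names(best)[is.na(best)]
  n_found <- length(found)
  status <- "absent"; contig_out <- NA_character_
  max_int <- NA_integer_; order_ok <- NA
  if (n_found > 0) {
    status <- "partial"
    g <- genome$genes |> arrange(contig, start)
    idx <- match(best[found], g$gene_id)
    cts <- g$contig[idx]
    if (n_found == length(queries) && length(unique(cts)) == 1) {
      contig_out <- unique(cts)
      on_ct <- which(g$contig == contig_out)
      ranks <- match(idx, on_ct)   # genomic position in query order
      gaps <- diff(sort(ranks)) - 1L
      max_int <- max(gaps)
      order_ok <- all(diff(ranks) > 0) || all(diff(ranks) < 0)
      if (all(gaps <= max_gap)) status <- "complete"
    }
  }
  tibble(genome = genome$id, status = status, n_found = n_found,
         found = paste(found, collapse = ","),
         missing = paste(missing, collapse = ","),
         contig = contig_out, max_intervening = max_int,
         order_conserved = order_ok)
}

#' Screen a cohort of genomes for a marker cluster
#'
#' @param genomes Named list of `genome_record`s (or a `complex_sim`).
#' @param queries Named, ordered `AAStringSet`.
#' @param ... Passed to [cluster_presence()].
#' @return Tibble, one row per genome.
#' @export
screen_cluster <- function(genomes, queries, ...) {
  if (inherits(genomes, "complex_sim")) genomes <- genomes$genomes
  bind_rows(lapply(genomes, cluster_presence, queries = queries, ...))
}
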