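# Seed-and-extend alignment core shared by the ANI and dDDH estimators.
#
# Strategy: the query genome is cut into fragments; exact seed k-mers taken
# at regular offsets across each fragment are matched against the subject
# (forward strand and reverse complement, concatenated with an N spacer)
# in one PDict pass. Each fragment is placed at its modal seed diagonal and
# extended ungapped there (mismatch counting); a banded local
# dynamic-programming alignment is used as fallback when the ungapped
# identity is poor, which is the only case where indels matter.

NUC_MAT <- NULL

nuc_submat <- function() {
  if (is.null(NUC_MAT)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace("NUC_MAT", m)
  }
  NUC_MAT
}

# subject = forward contigs + reverse complements, N-spaced so seeds cannot
# straddle a junction
build_subject <- function(rec, k) {
  spacer <- Biostrings::DNAStringSet(paste(rep("N", k), collapse = ""))
  ds <- rec$contigs
  all <- c(ds, spacer, Biostrings::reverseComplement(ds))
  Biostrings::DNAString(paste(vapply(seq_along(all), function(i)
    as.character(all[[i]]), character(1)), collapse = as.character(spacer[[1]])))
}

genome_fragments <- function(rec, fragment_length) {
  out <- list()
  for (ct in seq_along(rec$contigs)) {
    s <- rec$contigs[[ct]]
    len <- length(s)
    starts <- seq(1L, len, by = fragment_length)
    ends <- pmin(starts + fragment_length - 1L, len)
    out[[ct]] <- Biostrings::DNAStringSet(s, start = starts, end = ends)
  }
  do.call(c, out)
}

# modal seed diagonal per fragment; NA when no seed matches
seed_diagonals <- function(frags, subject, k, step) {
  n <- length(frags)
  widths <- Biostrings::width(frags)
  seed_frag <- integer(0); seed_off <- integer(0); seed_seq <- character(0)
  fr_chr <- as.character(frags)
  for (i in seq_len(n)) {
    w <- widths[i]
    if (w < k) next
    offs <- seq(1L, w - k + 1L, by = step)
    sq <- substring(fr_chr[i], offs, offs + k - 1L)
    ok <- !grepl("[^ACGT]", sq)
    seed_frag <- c(seed_frag, rep(i, sum(ok)))
    seed_off <- c(seed_off, offs[ok])
    seed_seq <- c(seed_seq, sq[ok])
  }
  diags <- rep(NA_integer_, n)
  if (!length(seed_seq)) return(diags)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed_seq))
  hits <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
  cand_frag <- rep.int(seed_frag, lengths(hits))
  cand_diag <- unlist(hits, use.names = FALSE) -
    rep.int(seed_off, lengths(hits)) + 1L
  if (!length(cand_frag)) return(diags)
  by_frag <- split(cand_diag, cand_frag)
  for (fi in names(by_frag)) {
    tb <- table(by_frag[[fi]])
    best <- names(tb)[tb == max(tb)]
    diags[as.integer(fi)] <- min(as.integer(best))
  }
  diags
}

# maximal-scoring contiguous segment of a +1/-penalty match profile
# (vectorized Kadane); returns NULL when nothing scores positive
best_segment <- function(eq, mismatch_penalty) {
  s <- ifelse(eq, 1, -mismatch_penalty)
  P <- cumsum(s)
  prefix0 <- c(0, P[-length(P)])
  cm <- cummin(prefix0)
  gains <- P - cm
  e_idx <- which.max(gains)
  if (gains[e_idx] <= 0) return(NULL)
  s_idx <- which(prefix0[seq_len(e_idx)] == cm[e_idx])[1]
  list(start = s_idx, end = e_idx, n_match = sum(eq[s_idx:e_idx]))
}

# per-fragment placement and identity against one subject genome.
# Extension at the modal diagonal is ungapped: the matched/mismatched
# profile is trimmed to its maximal-scoring segment (mismatch penalty 3,
# so uniformly diverged interiors are kept while unrelated tails -- e.g.
# rearrangement junctions -- are cut). A banded local DP fallback handles
# the rare fragments whose trimmed identity stays poor (indels).
frag_align_dir <- function(query_rec, subject, cfg) {
  frags <- genome_fragments(query_rec, cfg$fragment_length)
  widths <- Biostrings::width(frags)
  diags <- seed_diagonals(frags, subject, cfg$seed_kmer, cfg$seed_step)
  subj_chr <- as.character(subject)
  frag_chr <- as.character(frags)
  ls <- nchar(subj_chr)
  n <- length(frags)
  matches <- ov_len <- qspan <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    d <- diags[i]
    if (is.na(d)) next
    L <- widths[i]
    ov_s <- max(1L, d); ov_e <- min(ls, d + L - 1L)
    len <- ov_e - ov_s + 1L
    if (len < cfg$seed_kmer) next
    a <- charToRaw(substr(frag_chr[i], ov_s - d + 1L, ov_e - d + 1L))
    b <- charToRaw(substr(subj_chr, ov_s, ov_e))
    seg <- best_segment(a == b, 2)
    if (!is.null(seg)) {
      seg_len <- seg$end - seg$start + 1L
      ident <- seg$n_match / seg_len
      if (seg_len >= cfg$seed_kmer && ident >= cfg$gap_trigger) {
        matches[i] <- seg$n_match
        ov_len[i] <- seg_len
        qspan[i] <- seg_len
        next
      }
    }
    # banded DP fallback around the seed diagonal
    w_s <- max(1L, d - cfg$pad); w_e <- min(ls, d + L - 1L + cfg$pad)
    aln <- Biostrings::pairwiseAlignment(
      frags[[i]], Biostrings::subseq(subject, w_s, w_e),
      type = "local", substitutionMatrix = nuc_submat(),
      gapOpening = 5, gapExtension = 2)
    al_len <- Biostrings::nchar(aln)
    if (al_len >= cfg$seed_kmer) {
      matches[i] <- Biostrings::nmatch(aln)
      ov_len[i] <- al_len
      qspan[i] <- Biostrings::end(Biostrings::pattern(aln)) -
        Biostrings::start(Biostrings::pattern(aln)) + 1
    }
  }
  tibble(
    frag_len = widths,
    ov_len = ov_len,
    matches = matches,
    identity = matches / ov_len,
    coverage = qspan / widths,
    aligned = !is.na(ov_len)
  )
}
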