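#' Configuration for fragment-based genome comparison
#'
#' Parameters of the fragment ANI / dDDH estimators. Defaults follow the
#' classical fragment-based ANI definition: 1,020-nt query fragments,
#' fragments retained when their alignment reaches at least 30% identity
#' over at least 70% of the fragment.
#'
#' @param fragment_length Query fragment size in nt.
#' @param min_fragment_identity Minimum identity fraction to retain a
#'   fragment for ANI.
#' @param min_fragment_coverage Minimum fraction of the fragment that must
#'   align.
#' @param seed_kmer Exact-match seed length for alignment placement.
#' @param seed_step Offset step between successive seeds along a fragment.
#' @param gap_trigger Ungapped identity below which the banded
#'   dynamic-programming fallback is used.
#' @param pad Band half-width (nt) for the fallback alignment window.
#' @return An `ani_config` list.
#' @export
ani_config <- function(fragment_length = 1020,
                       min_fragment_identity = 0.30,
                       min_fragment_coverage = 0.70,
                       seed_kmer = 15,
                       seed_step = 60,
                       gap_trigger = 0.65,
                       pad = 30) {
  assert_that(min_fragment_identity > 0 && min_fragment_identity <= 1,
              "min_fragment_identity must be in (0, 1]")
  assert_that(min_fragment_coverage > 0 && min_fragment_coverage <= 1,
              "min_fragment_coverage must be in (0, 1]")
  assert_that(fragment_length >= seed_kmer,
              "fragment_length must be >= seed_kmer")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_fragment_identity = min_fragment_identity,
                 min_fragment_coverage = min_fragment_coverage,
                 seed_kmer = as.integer(seed_kmer),
                 seed_step = as.integer(seed_step),
                 gap_trigger = gap_trigger,
                 pad = as.integer(pad)),
            class = "ani_config")
}

ani_from_frags <- function(fr, cfg) {
  keep <- fr$aligned & fr$identity >= cfg$min_fragment_identity &
    fr$coverage >= cfg$min_fragment_coverage
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(list(ani = NA_real_, frac = 0))
  list(ani = mean(fr$identity[keep]) * 100, frac = mean(keep))
}

ggdc_from_frags <- function(fr, cfg) {
  keep <- fr$aligned & fr$identity >= cfg$min_fragment_identity
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) return(NA_real_)
  1 - sum(fr$matches[keep]) / sum(fr$ov_len[keep])
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' Cuts each genome into fragments, places each fragment on the other genome
#' by exact k-mer seeding and extends at the modal seed diagonal; fragments
#' passing the identity/coverage filters contribute their identity. The
#' symmetrized ANI is the mean of the two directions. When no fragment is
#' retained in either direction the ANI is undefined and reported as `NA`
#' (an explicit no-alignment marker, never 0).
#'
#' @param a,b `genome_record` objects.
#' @param cfg An [ani_config()].
#' @return One-row tibble: genome_a, genome_b, ani_percent (symmetrized),
#'   ani_ab, ani_ba, aligned_fraction.
#' @export
fragment_ani <- function(a, b, cfg = ani_config()) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  sub_b <- build_subject(b, cfg$seed_kmer)
  sub_a <- build_subject(a, cfg$seed_kmer)
  ab <- ani_from_frags(frag_align_dir(a, sub_b, cfg), cfg)
  ba <- ani_from_frags(frag_align_dir(b, sub_a, cfg), cfg)
  vals <- c(ab$ani, ba$ani)
  tibble(
    genome_a = a$id, genome_b = b$id,
    ani_percent = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
    ani_ab = ab$ani, ani_ba = ba$ani,
    aligned_fraction = mean(c(ab$frac, ba$frac))
  )
}

# logistic map pinned to d = 0 -> 99.9% and d = d_mid -> ddh_mid%
ddh_map_coef <- function(ddh0 = 99.9, d_mid = 0.05, ddh_mid = 60) {
  a <- log(100 / ddh0 - 1)
  b <- (log(100 / ddh_mid - 1) - a) / d_mid
  c(a = a, b = b)
}

#' Map an intergenomic distance to a dDDH percentage
#'
#' Two-parameter logistic, strictly decreasing in `d`, anchored by default at
#' d = 0 -> 99.9% and d = 0.05 -> 60% (the observed correspondence of ~95%
#' ANI with ~60% dDDH at the genomovar scale). Coefficients are solved in
#' closed form from the anchors and fully user-overridable.
#'
#' @param d Intergenomic distance(s) in `[0, 1]`.
#' @param coef Named vector `c(a, b)` as from `ddh_map_coef()`.
#' @return dDDH percentage(s).
#' @export
ddh_from_distance <- function(d, coef = ddh_map_coef()) {
  100 / (1 + exp(coef[["a"]] + coef[["b"]] * d))
}

#' GGDC-style intergenomic distance and dDDH estimate
#'
#' Collects local matches (HSPs) between the two genomes with the same
#' seed-and-extend engine as [fragment_ani()] and computes
#' d = 1 - (summed identities / summed HSP length), a distance independent
#' of total genome length by construction, then maps it to a dDDH percentage
#' with [ddh_from_distance()]. Directions are averaged.
#'
#' @inheritParams fragment_ani
#' @param map Logistic map coefficients (see [ddh_from_distance()]).
#' @return One-row tibble: genome_a, genome_b, d, ddh_percent, ci_halfwidth
#'   (`NA`; reported for interface compatibility, not computed).
#' @export
ggdc_distance <- function(a, b, cfg = ani_config(), map = ddh_map_coef()) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  d_ab <- ggdc_from_frags(frag_align_dir(a, build_subject(b, cfg$seed_kmer), cfg), cfg)
  d_ba <- ggdc_from_frags(frag_align_dir(b, build_subject(a, cfg$seed_kmer), cfg), cfg)
  d <- if (all(is.na(c(d_ab, d_ba)))) NA_real_ else mean(c(d_ab, d_ba), na.rm = TRUE)
  tibble(genome_a = a$id, genome_b = b$id, d = d,
         ddh_percent = ddh_from_distance(d, map),
         ci_halfwidth = NA_real_)
}

# ---- TETRA -----------------------------------------------------------------

tetra_zscores <- function(rec) {
  ds <- c(rec$contigs, Biostrings::reverseComplement(rec$contigs))
  n4 <- colSums(Biostrings::oligonucleotideFrequency(ds, 4))
  n3 <- colSums(Biostrings::oligonucleotideFrequency(ds, 3))
  n2 <- colSums(Biostrings::oligonucleotideFrequency(ds, 2))
  w <- names(n4)
  exp4 <- ifelse(n2[substr(w, 2, 3)] > 0,
                 n3[substr(w, 1, 3)] * n3[substr(w, 2, 4)] / n2[substr(w, 2, 3)],
                 0)
  z <- ifelse(exp4 > 0, (n4 - exp4) / sqrt(exp4), 0)
  stats::setNames(as.numeric(z), w)
}

#' Tetranucleotide usage correlation between two genomes
#'
#' Tetranucleotide counts (sequence plus reverse complement; windows with
#' ambiguous bases are not counted) are compared against order-2 Markov
#' expectations E(w1w2w3w4) = n(w1w2w3) n(w2w3w4) / n(w2w3); z-scores
#' (obs - exp)/sqrt(exp) over the 256 words are correlated between genomes
#' (Pearson). Values > 0.99 conventionally support conspecificity.
#'
#' @inheritParams fragment_ani
#' @return One-row tibble: genome_a, genome_b, r. `r` is `NA` with a warning
#'   for degenerate (zero-variance) signatures.
#' @export
tetra_corr <- function(a, b) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  for (g in list(a, b)) {
    assert_that(sum(Biostrings::width(g$contigs)) >= 2000,
                "TETRA requires at least 2 kb of sequence per genome")
  }
  za <- tetra_zscores(a); zb <- tetra_zscores(b)
  if (stats::sd(za) < 1e-6 || stats::sd(zb) < 1e-6) {
    warn("degenerate tetranucleotide signature: undefined variance")
    return(tibble(genome_a = a$id, genome_b = b$id, r = NA_real_))
  }
  tibble(genome_a = a$id, genome_b = b$id, r = stats::cor(za, zb))
}

# ---- distance matrices -----------------------------------------------------

METRIC_SELF <- c(ani = 100, ani_dist = 0, ddh = 100, ggdc_d = 0, tetra = 1,
                 homolog_fraction = 100, core_p_distance = 0)

#' Labeled square matrix of a pairwise genome metric
#'
#' @param values Square numeric matrix with identical row/column labels.
#' @param metric Metric name tag (e.g. "ani", "ani_dist", "ddh", "tetra").
#' @return A `dist_matrix`.
#' @export
new_dist_matrix <- function(values, metric) {
  values <- as.matrix(values)
  assert_that(nrow(values) == ncol(values), "matrix must be square")
  assert_that(!is.null(rownames(values)) &&
                identical(rownames(values), colnames(values)),
              "row and column labels must match")
  assert_that(!anyDuplicated(rownames(values)), "duplicate labels rejected")
  structure(values, metric = metric, class = c("dist_matrix", class(values)))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("<dist_matrix> metric '%s', %d genomes\n",
              attr(x, "metric"), nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Long-format export of a distance matrix
#'
#' Emits the full square: N genomes produce N^2 rows (self-pairs and both
#' orders included), matching the convention in which 123 genomes yield
#' 15,129 pairwise values.
#'
#' @param x A `dist_matrix`.
#' @param ... Unused.
#' @return Tibble with columns genome_a, genome_b, metric, value.
#' @export
as_tibble.dist_matrix <- function(x, ...) {
  labs <- rownames(x)
  tibble(
    genome_a = rep(labs, times = length(labs)),
    genome_b = rep(labs, each = length(labs)),
    metric = attr(x, "metric"),
    value = as.numeric(unclass(x))
  )
}

#' Pairwise metric matrix over a genome set
#'
#' Computes the chosen metric for every unordered pair, symmetrizes
#' (mean of the two directions where directional), and fixes the diagonal at
#' the metric's self-value (ANI 100, 100-ANI 0, dDDH 100, TETRA 1).
#'
#' @param genomes Named list of `genome_record`s (>= 2, unique labels).
#' @param metric One of "ani", "ani_dist" (100-ANI), "ddh", "ggdc_d",
#'   "tetra".
#' @param cfg An [ani_config()] (ignored for "tetra").
#' @param map dDDH logistic coefficients for "ddh".
#' @return A `dist_matrix`.
#' @export
build_matrix <- function(genomes, metric = c("ani", "ani_dist", "ddh",
                                             "ggdc_d", "tetra"),
                         cfg = ani_config(), map = ddh_map_coef()) {
  metric <- match.arg(metric)
  if (metric %in% c("ani", "ani_dist", "ddh", "ggdc_d")) {
    gd <- genome_distances(genomes, cfg, map)
    return(switch(metric, ani = gd$ani, ani_dist = gd$ani_dist,
                  ddh = gd$ddh, ggdc_d = gd$ggdc_d))
  }
  labs <- names(genomes)
  assert_that(length(labs) >= 2, "need at least 2 genomes")
  assert_that(!anyDuplicated(labs), "duplicate labels rejected")
  m <- matrix(METRIC_SELF[[metric]], length(labs), length(labs),
              dimnames = list(labs, labs))
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      v <- tetra_corr(genomes[[i]], genomes[[j]])$r
      m[i, j] <- m[j, i] <- v
    }
  }
  new_dist_matrix(m, metric)
}

#' All fragment-based metrics in one pass
#'
#' Runs the seed-and-extend engine once per ordered genome pair and derives
#' ANI, 100-ANI, the GGDC-style distance and dDDH from the shared fragment
#' alignments.
#'
#' @inheritParams build_matrix
#' @return List of `dist_matrix` objects (`ani`, `ani_dist`, `ggdc_d`,
#'   `ddh`) plus `long`, a tibble of both directed values per pair.
#' @export
genome_distances <- function(genomes, cfg = ani_config(),
                             map = ddh_map_coef()) {
  labs <- names(genomes)
  assert_that(length(labs) >= 2, "need at least 2 genomes")
  assert_that(!anyDuplicated(labs), "duplicate labels rejected")
  n <- length(labs)
  subjects <- lapply(genomes, build_subject, k = cfg$seed_kmer)
  ani_m <- matrix(100, n, n, dimnames = list(labs, labs))
  d_m <- matrix(0, n, n, dimnames = list(labs, labs))
  long <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      fr <- frag_align_dir(genomes[[i]], subjects[[j]], cfg)
      av <- ani_from_frags(fr, cfg)
      dv <- ggdc_from_frags(fr, cfg)
      long[[length(long) + 1L]] <- tibble(
        genome_a = labs[i], genome_b = labs[j],
        ani = av$ani, aligned_fraction = av$frac, ggdc_d = dv)
    }
  }
  long <- bind_rows(long)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sub <- long[(long$genome_a == labs[i] & long$genome_b == labs[j]) |
                    (long$genome_a == labs[j] & long$genome_b == labs[i]), ]
      ani_m[i, j] <- ani_m[j, i] <- mean(sub$ani, na.rm = TRUE)
      d_m[i, j] <- d_m[j, i] <- mean(sub$ggdc_d, na.rm = TRUE)
    }
  }
  ddh_m <- ddh_from_distance(d_m, map)
  diag(ddh_m) <- 100
  dimnames(ddh_m) <- dimnames(d_m)
  list(
    ani = new_dist_matrix(ani_m, "ani"),
    ani_dist = new_dist_matrix(100 - ani_m, "ani_dist"),
    ggdc_d = new_dist_matrix(d_m, "ggdc_d"),
    ddh = new_dist_matrix(ddh_m, "ddh"),
    long = long
  )
}
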