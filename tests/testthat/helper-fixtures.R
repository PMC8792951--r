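# Shared, lazily built fixtures. test_dir() runs all files in one session,
# so expensive objects (the default synthetic complex and its distance
# matrices) are computed once and reused.

.fx <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

# the study's default synthetic complex: 3 genomovars x 4 genomes, marker
# cluster implanted, one genome lacking the first marker gene
fixture_config <- function() {
  sim_config(n_genomovars = 3, genomes_per_genomovar = 4,
             root_families = 200, gain_rate = 600, loss_rate = 2,
             within_divergence = 0.01, between_divergence = 0.08,
             implant_cluster = TRUE, drop_cluster_gene_in = "gv02_s03",
             seed = 101)
}

fixture_sim <- function() fx("sim", simulate_complex(fixture_config()))

fixture_report <- function() {
  fx("report", run_complex_analysis(
    fixture_sim(), pipeline_config(n_random_trees = 1000, seed = 7)))
}

# small complex with outgroups for membership screening
fixture_membership_sim <- function() {
  fx("msim", simulate_complex(sim_config(
    n_genomovars = 2, genomes_per_genomovar = 3, root_families = 120,
    gain_rate = 150, loss_rate = 2, n_outgroups = 2,
    outgroup_divergence = 0.2, seed = 202)))
}

fixture_membership_dists <- function() {
  fx("mdists", genome_distances(fixture_membership_sim()$genomes))
}

# deterministic random protein (uniform alphabet, no shared structure)
random_protein <- function(n, seed = NULL) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  if (!is.null(seed)) set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# a genome_record assembled from explicit gene sequences (plus strand,
# single contig) -- lets tests control annotations exactly
make_record <- function(id, gene_seqs, strands = NULL) {
  n <- length(gene_seqs)
  strands <- strands %||% rep("+", n)
  widths <- nchar(gene_seqs)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  on_contig <- vapply(seq_len(n), function(i) {
    if (strands[i] == "+") gene_seqs[i] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gene_seqs[i])))
  }, character(1))
  contig <- Biostrings::DNAStringSet(paste(on_contig, collapse = ""))
  names(contig) <- paste0(id, "_c01")
  genes <- tibble::tibble(
    gene_id = sprintf("%s_%04d", id, seq_len(n)),
    contig = names(contig), start = starts, end = ends,
    strand = strands,
    family = names(gene_seqs) %||% sprintf("F%05d", seq_len(n)),
    rank = seq_len(n))
  prot <- vapply(gene_seqs, function(s)
    gsub("\\*", "X", as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1, 3 * (nchar(s) %/% 3)))))),
    character(1))
  proteins <- Biostrings::AAStringSet(unname(prot))
  names(proteins) <- genes$gene_id
  genome_record(id, contig, genes, proteins)
}

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutate_dna <- function(s, p_diff, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- strsplit(s, "")[[1]]
  idx <- which(stats::runif(length(v)) < p_diff)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

`%||%` <- rlang::`%||%`
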