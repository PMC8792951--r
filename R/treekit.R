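#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via \pkg{ape}) on a symmetric zero-diagonal
#' matrix such as the 100-ANI transform or the GGDC distance. Labels are
#' sorted before clustering so tie-breaking is deterministic; negative
#' branch lengths are clamped to 0.
#'
#' @param m A `dist_matrix` (or plain labeled symmetric matrix), N >= 3.
#' @return An unrooted `phylo`.
#' @export
nj_tree <- function(m) {
  mm <- unclass(m)
  assert_that(nrow(mm) >= 3, "neighbor-joining needs at least 3 genomes")
  assert_that(max(abs(mm - t(mm))) < 1e-8, "matrix must be symmetric")
  assert_that(max(abs(diag(mm))) < 1e-8, "diagonal must be zero")
  ord <- order(rownames(mm))
  mm <- mm[ord, ord]
  tr <- ape::nj(stats::as.dist(mm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise p-distance on concatenated single-copy core genes
#'
#' Extracts each single-copy core family's coding sequence from every
#' genome, projects unequal-length members onto a common reference with the
#' built-in global aligner, concatenates the per-family alignments and
#' computes pairwise proportion distances (gap-containing columns excluded
#' pairwise).
#'
#' @param genomes Named list of `genome_record`s (or a `complex_sim`).
#' @param families Either a `homolog_families` membership tibble (family,
#'   genome, gene) from [cluster_homologs()], or a character vector of
#'   family names matched against the `family` column of each genome's
#'   gene table. Only families single-copy in every genome are used (e.g.
#'   restrict with [single_copy_core()] ids via `core`).
#' @param core Optional character vector restricting to these family ids.
#' @return A `dist_matrix` (metric "core_p_distance").
#' @export
concat_core_distance <- function(genomes, families, core = NULL) {
  if (inherits(genomes, "complex_sim")) genomes <- genomes$genomes
  labs <- names(genomes)
  if (is.character(families)) {
    # annotation route: look up the genes' own family column
    membership <- bind_rows(lapply(genomes, function(g)
      tibble(family = g$genes$family, genome = g$id,
             gene = g$genes$gene_id))) |>
      filter(family %in% families)
  } else {
    membership <- as_tibble(families[, c("family", "genome", "gene")])
  }
  if (!is.null(core)) membership <- filter(membership, family %in% core)
  ok <- membership |>
    count(family, genome) |>
    group_by(family) |>
    summarise(usable = n() == length(labs) && all(n == 1), .groups = "drop") |>
    filter(usable)
  fam_use <- sort(ok$family)
  assert_that(length(fam_use) >= 1,
              "no single-copy core families: build a larger or less diverged dataset")
  gene_of <- membership |> filter(family %in% fam_use)
  blocks <- lapply(fam_use, function(fam) {
    rows <- gene_of[gene_of$family == fam, ]
    seqs <- vapply(labs, function(gn) {
      g <- genomes[[gn]]
      gid <- rows$gene[rows$genome == gn]
      row <- g$genes[g$genes$gene_id == gid, ]
      s <- as.character(Biostrings::subseq(g$contigs[[row$contig]],
                                           row$start, row$end))
      if (row$strand == "-") s <- revcomp_chr(s)
      s
    }, character(1))
    widths <- nchar(seqs)
    if (length(unique(widths)) > 1) {
      ref <- seqs[which.max(widths)]
      seqs <- vapply(seqs, function(s) {
        if (nchar(s) == nchar(ref)) return(s)
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(s), Biostrings::DNAString(ref),
          type = "global", substitutionMatrix = nuc_submat(),
          gapOpening = 5, gapExtension = 2)
        # pattern projected onto reference coordinates
        as.character(Biostrings::aligned(aln))
      }, character(1))
    }
    seqs
  })
  concat <- vapply(seq_along(labs), function(i)
    paste(vapply(blocks, `[`, character(1), i), collapse = ""), character(1))
  mat <- do.call(rbind, strsplit(concat, ""))
  rownames(mat) <- labs
  d <- ape::dist.dna(ape::as.DNAbin(mat), model = "raw",
                     pairwise.deletion = TRUE)
  m <- as.matrix(d)
  new_dist_matrix(m[labs, labs], "core_p_distance")
}

# Kendall-Colijn vector: for each unordered leaf pair (sorted canonically)
# the root-to-MRCA depth, blended between topological (edge count) and
# branch-length depth by lambda; plus one pendant entry per leaf.
kc_vector <- function(tree, lambda = 0) {
  assert_that(ape::is.rooted(tree), "tree must be rooted")
  ntip <- length(tree$tip.label)
  ord <- order(tree$tip.label)
  depth_len <- ape::node.depth.edgelength(tree)
  # topological depth: edges from root
  topo <- rep(0L, ntip + tree$Nnode)
  eo <- edges_preorder(tree)
  for (e in seq_len(nrow(eo$edge))) {
    topo[eo$edge[e, 2]] <- topo[eo$edge[e, 1]] + 1L
  }
  mr <- ape::mrca(tree)
  pend <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
  v <- c()
  for (a in seq_len(ntip - 1)) {
    for (b in (a + 1):ntip) {
      i <- ord[a]; j <- ord[b]
      anc <- mr[i, j]
      v <- c(v, (1 - lambda) * topo[anc] + lambda * depth_len[anc])
    }
  }
  c(v, (1 - lambda) * 1 + lambda * pend[ord])
}

#' Kendall-Colijn distance between two rooted trees
#'
#' Euclidean distance between the trees' root-to-MRCA depth vectors over all
#' leaf pairs. At `lambda = 0` only topology is weighed; `lambda = 1` weighs
#' only branch lengths.
#'
#' @param t1,t2 Rooted `phylo` objects on the same leaf set.
#' @param lambda Topology/length blending in `[0, 1]`.
#' @return Non-negative numeric distance.
#' @export
kc_distance <- function(t1, t2, lambda = 0) {
  assert_that(setequal(t1$tip.label, t2$tip.label),
              "trees must share the same leaf set")
  sqrt(sum((kc_vector(t1, lambda) - kc_vector(t2, lambda))^2))
}

#' Topology concordance test against a random-tree null
#'
#' Compares the Kendall-Colijn distance between query and reference with the
#' distances from the reference to random rooted trees (coalescent-style
#' random joins with shuffled labels). A one-sided z-test asks whether the
#' query is closer to the reference than random trees are; small p means the
#' two trees agree more than chance.
#'
#' @param query,reference Rooted `phylo` objects on the same leaf set.
#' @param n_random Number of random background trees (>= 100).
#' @param seed Optional seed.
#' @param lambda Kendall-Colijn lambda (default 0: topology only).
#' @return One-row tibble: statistic (z), p_value, d_obs, null_mean,
#'   null_sd, n_random.
#' @export
kc_null_test <- function(query, reference, n_random = 1000, seed = NULL,
                         lambda = 0) {
  assert_that(n_random >= 100, "n_random < 100 gives an unstable null")
  assert_that(setequal(query$tip.label, reference$tip.label),
              "trees must share the same leaf set")
  d_obs <- kc_distance(query, reference, lambda)
  labs <- reference$tip.label
  ref_v <- kc_vector(reference, lambda)
  with_seed(seed, {
    d_null <- vapply(seq_len(n_random), function(i) {
      rt <- ape::rcoal(length(labs), tip.label = sample(labs))
      sqrt(sum((kc_vector(rt, lambda) - ref_v)^2))
    }, numeric(1))
    z <- (d_obs - mean(d_null)) / stats::sd(d_null)
    tibble(statistic = z, p_value = stats::pnorm(z), d_obs = d_obs,
           null_mean = mean(d_null), null_sd = stats::sd(d_null),
           n_random = n_random)
  })
}

#' Delineate genomovars from ANI and dDDH matrices
#'
#' Places an edge between two genomes when ANI >= `ani_t` and
#' dDDH >= `ddh_t`; genomovars are the connected components (single
#' linkage), numbered stably by their lexicographically smallest member.
#' Default cutoffs sit just below the ~95% ANI / ~60% dDDH rule so that a
#' borderline pair at ANI 94.89 / dDDH 59.9 is still grouped together.
#'
#' @param ani,ddh `dist_matrix` objects with identical labels.
#' @param ani_t,ddh_t Percent thresholds.
#' @return A `genomovar_assignment` tibble (genome, genomovar) with the
#'   thresholds and edge list as attributes.
#' @export
delineate_genomovars <- function(ani, ddh, ani_t = 94.5, ddh_t = 59.5) {
  labs <- rownames(ani)
  assert_that(identical(labs, rownames(ddh)),
              "ANI and dDDH matrices must share labels")
  adj <- (unclass(ani) >= ani_t) & (unclass(ddh) >= ddh_t)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "max")
  memb <- igraph::components(g)$membership
  smallest <- vapply(split(labs, memb), min, character(1))
  comp_order <- rank(smallest)
  gv <- sprintf("gv%02d", comp_order[as.character(memb)])
  ew <- which(adj & upper.tri(adj), arr.ind = TRUE)
  out <- tibble(genome = labs, genomovar = gv) |> arrange(genome)
  structure(out, class = c("genomovar_assignment", class(out)),
            ani_t = ani_t, ddh_t = ddh_t,
            edges = tibble(genome_a = labs[ew[, 1]], genome_b = labs[ew[, 2]]))
}

#' Screen candidate genomes for species-complex membership
#'
#' A candidate is a member iff its best ANI against the references reaches
#' `prefilter_ani` AND it falls inside the smallest clade containing all
#' references in both the 100-ANI NJ tree and the concatenated-core-distance
#' NJ tree (both rooted on `outgroup`).
#'
#' @param ani ANI `dist_matrix` over candidates + references (+ outgroup).
#' @param core_dist Core p-distance `dist_matrix` over the same labels.
#' @param references Character vector of reference genome labels.
#' @param outgroup Leaf label(s) used to root both trees; must not be
#'   references.
#' @param prefilter_ani ANI retention threshold (percent).
#' @return Tibble: genome, max_ref_ani, pass_prefilter, in_ani_clade,
#'   in_core_clade, member.
#' @export
membership_screen <- function(ani, core_dist, references, outgroup,
                              prefilter_ani = 80) {
  labs <- rownames(ani)
  assert_that(length(references) >= 1, "need at least one reference")
  assert_that(all(references %in% labs), "unknown reference label")
  assert_that(all(outgroup %in% labs), "outgroup absent from matrix")
  clade_members <- function(m) {
    tr <- nj_tree(m)
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    anc <- ape::getMRCA(tr, references)
    if (is.null(anc)) return(references)  # single reference
    desc <- ape::extract.clade(tr, anc)$tip.label
    desc
  }
  in_ani <- labs %in% clade_members(new_dist_matrix(100 - unclass(ani), "ani_dist"))
  in_core <- labs %in% clade_members(core_dist)
  max_ani <- vapply(labs, function(g) {
    if (g %in% references && length(references) == 1) return(100)
    max(unclass(ani)[g, setdiff(references, g)])
  }, numeric(1))
  tibble(genome = labs, max_ref_ani = max_ani,
         pass_prefilter = max_ani >= prefilter_ani,
         in_ani_clade = in_ani, in_core_clade = in_core,
         member = max_ani >= prefilter_ani & in_ani & in_core)
}

#' Check declared names against genomovar assignments
#'
#' Each genomovar inherits the species name of its reference strains (if
#' any). Verdicts: `consistent` (declared name matches), `misidentified`
#' (conflict), `newly_assigned` (declared "sp."/unknown, now resolvable),
#' `novel_genomovar` (component without any reference strain).
#'
#' @param assignment A `genomovar_assignment`.
#' @param declared Named character vector genome -> declared species name
#'   ("sp.", "" or NA meaning unassigned).
#' @param reference_names Named character vector: reference genome ->
#'   authoritative species name.
#' @return A `taxonomy_report` tibble with a `summary` attribute of verdict
#'   counts.
#' @export
taxonomy_report <- function(assignment, declared, reference_names) {
  stopifnot(inherits(assignment, "genomovar_assignment"))
  assert_that(all(assignment$genome %in% names(declared)),
              "every genome needs a declared name")
  comp_name <- assignment |>
    filter(genome %in% names(reference_names)) |>
    mutate(ref = reference_names[genome]) |>
    group_by(genomovar) |>
    summarise(genomovar_name = sort(unique(ref))[1],
              ambiguous = length(unique(ref)) > 1, .groups = "drop")
  if (any(comp_name$ambiguous)) {
    warn("genomovar(s) containing references with conflicting names; using first")
  }
  out <- assignment |>
    left_join(comp_name |> select(genomovar, genomovar_name), by = "genomovar") |>
    mutate(
      declared_name = unname(declared[genome]),
      unassigned = is.na(declared_name) | declared_name %in% c("", "sp."),
      verdict = case_when(
        is.na(genomovar_name) ~ "novel_genomovar",
        unassigned ~ "newly_assigned",
        declared_name == genomovar_name ~ "consistent",
        TRUE ~ "misidentified"
      )
    ) |>
    select(genome, declared_name, genomovar, genomovar_name, verdict)
  structure(out, class = c("taxonomy_report", class(out)),
            summary = out |> count(verdict))
}

#' Per-genome summary statistics and a two-group GC% comparison
#'
#' @param genomes Named list of `genome_record`s (or a `complex_sim`).
#' @param groups Optional named character vector genome -> group name (two
#'   groups); Welch's t-test is run on GC% between the two groups when both
#'   have >= 2 members.
#' @return Tibble (genome, length_bp, gc_percent, n_cds); the `htest` result
#'   is attached as attribute `gc_test` when computed.
#' @export
genome_stats <- function(genomes, groups = NULL) {
  if (inherits(genomes, "complex_sim")) genomes <- genomes$genomes
  stats_tbl <- bind_rows(lapply(genomes, function(g) {
    freq <- colSums(Biostrings::letterFrequency(g$contigs, c("A", "C", "G", "T")))
    tibble(genome = g$id,
           length_bp = sum(Biostrings::width(g$contigs)),
           gc_percent = 100 * (freq[["C"]] + freq[["G"]]) / sum(freq),
           n_cds = nrow(g$genes))
  }))
  test <- NULL
  if (!is.null(groups)) {
    grp <- groups[stats_tbl$genome]
    tab <- table(grp)
    if (length(tab) == 2 && all(tab >= 2)) {
      test <- stats::t.test(stats_tbl$gc_percent ~ grp)
    } else {
      warn("need two groups with >= 2 genomes each; stats only")
    }
  }
  structure(stats_tbl, gc_test = test)
}
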