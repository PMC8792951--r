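#' Configuration for a synthetic species-complex simulation
#'
#' Bundles and validates all parameters of the synthetic genome-complex
#' generator. The generator emulates the statistical structure that
#' genome-based taxonomy assumes: several genomovar clades with high
#' within-clade and lower between-clade nucleotide identity, gene content
#' evolving by gain and loss along the phylogeny, and an optional implanted
#' five-gene ordered marker cluster (an ectoine-operon analogue).
#'
#' @param n_genomovars Number of genomovar clades (>= 1).
#' @param genomes_per_genomovar Genomes per clade (>= 1).
#' @param root_families Ancestral gene-family repertoire size.
#' @param gain_rate Genome-wide family innovations per unit branch length.
#' @param loss_rate Per-family loss rate per unit branch length.
#' @param within_divergence Substitutions/site from a genomovar ancestor to
#'   its leaves, so within-genomovar leaf pairs sit at about twice this value.
#' @param between_divergence Substitutions/site from the complex root to the
#'   leaves; between-genomovar paths are at least twice this value.
#' @param gene_length Gene length in nucleotides; must be divisible by 3.
#' @param implant_cluster Implant the ordered 5-gene marker cluster?
#' @param drop_cluster_gene_in Genome ids in which the first marker gene is
#'   deleted (emulates strains lacking the first cluster gene).
#' @param n_contigs Contigs per genome; values > 1 fragment the genome at
#'   gene boundaries to emulate draft assemblies.
#' @param n_outgroups Number of distant outgroup genomes attached basally
#'   (genomovar label "out"); their leaves sit `outgroup_divergence`
#'   substitutions/site from the root.
#' @param outgroup_divergence Root-to-outgroup-leaf divergence.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including this seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genomovars = 3,
                       genomes_per_genomovar = 4,
                       root_families = 200,
                       gain_rate = 600,
                       loss_rate = 2,
                       within_divergence = 0.01,
                       between_divergence = 0.08,
                       gene_length = 900,
                       implant_cluster = FALSE,
                       drop_cluster_gene_in = character(),
                       n_contigs = 1,
                       n_outgroups = 0,
                       outgroup_divergence = 0.2,
                       seed = 1L) {
  assert_that(n_genomovars >= 1, "n_genomovars must be >= 1")
  assert_that(genomes_per_genomovar >= 1, "genomes_per_genomovar must be >= 1")
  assert_that(root_families >= 1, "root_families must be >= 1")
  assert_that(gain_rate >= 0 && loss_rate >= 0, "rates must be >= 0")
  assert_that(within_divergence >= 0 && between_divergence >= 0,
              "divergences must be >= 0")
  assert_that(gene_length >= 30, "gene_length must be >= 30")
  assert_that(gene_length %% 3 == 0, "gene_length must be divisible by 3")
  if (n_genomovars > 1) {
    assert_that(between_divergence > within_divergence,
                "between_divergence must exceed within_divergence")
  }
  if (n_outgroups > 0) {
    assert_that(outgroup_divergence > 1.1 * between_divergence,
                "outgroup_divergence must exceed 1.1 * between_divergence")
  }
  structure(list(
    n_genomovars = as.integer(n_genomovars),
    genomes_per_genomovar = as.integer(genomes_per_genomovar),
    root_families = as.integer(root_families),
    gain_rate = gain_rate,
    loss_rate = loss_rate,
    within_divergence = within_divergence,
    between_divergence = between_divergence,
    gene_length = as.integer(gene_length),
    implant_cluster = isTRUE(implant_cluster),
    drop_cluster_gene_in = as.character(drop_cluster_gene_in),
    n_contigs = as.integer(n_contigs),
    n_outgroups = as.integer(n_outgroups),
    outgroup_divergence = outgroup_divergence,
    seed = as.integer(seed)
  ), class = "sim_config")
}

MARKER_GENES <- c("ectA", "ectB", "ectC", "ectD", "ask_ect")

node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- tree$node.label
  if (is.null(nl)) nl <- paste0("n", (ntip + 1L):(ntip + tree$Nnode))
  c(tree$tip.label, nl)
}

# cladewise edge matrix guarantees parents are visited before children
edges_preorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "cladewise")
  list(edge = tr$edge, length = tr$edge.length)
}

rand_clade <- function(labels, depth) {
  n <- length(labels)
  if (n == 1) return(labels)
  st <- ape::rcoal(n, tip.label = labels)
  h <- max(ape::branching.times(st))
  st$edge.length <- if (depth == 0 || h == 0) rep(0, length(st$edge.length)) else
    st$edge.length * (depth / h)
  sub("; *$", "", ape::write.tree(st))
}

#' Simulate the species-complex phylogeny
#'
#' Generates a rooted binary ultrametric tree with one clade per genomovar.
#' Leaves of the same genomovar lie at path distance about twice
#' `within_divergence`; leaves of different genomovars at least twice
#' `between_divergence` apart (backbone nodes sit within 10% of
#' `between_divergence` of the root).
#'
#' @param config A [sim_config()].
#' @return A list with `tree` (an `ape::phylo`, rooted, with internal node
#'   labels) and `labels`, a tibble mapping `genome` to `genomovar`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    g <- config$n_genomovars
    m <- config$genomes_per_genomovar
    within <- config$within_divergence
    between <- config$between_divergence
    ids <- lapply(seq_len(g), function(i)
      sprintf("gv%02d_s%02d", i, seq_len(m)))
    labels <- tibble(
      genome = unlist(ids),
      genomovar = rep(sprintf("gv%02d", seq_len(g)), each = m)
    )
    tip_age <- if (m >= 2) within else 0
    if (g == 1) {
      nwk <- paste0(if (m == 1) ids[[1]] else rand_clade(ids[[1]], within), ";")
    } else {
      d_max <- 0.1 * between
      D <- between + d_max
      ph <- sprintf("GVT%03dX", seq_len(g))
      bb <- if (g == 2) {
        # deterministic cherry; rcoal(2) topology is unique anyway
        ape::read.tree(text = sprintf("(%s:1,%s:1);", ph[1], ph[2]))
      } else ape::rcoal(g, tip.label = ph)
      ages <- ape::branching.times(bb)
      A <- max(ages)
      new_age <- (D - d_max) + d_max * (ages / A)
      age_of <- function(node) {
        if (node <= g) tip_age else new_age[as.character(node)]
      }
      bb$edge.length <- vapply(seq_len(nrow(bb$edge)), function(e) {
        age_of(bb$edge[e, 1]) - age_of(bb$edge[e, 2])
      }, numeric(1))
      nwk <- ape::write.tree(bb)
      for (i in seq_len(g)) {
        rep_str <- if (m == 1) ids[[i]] else rand_clade(ids[[i]], within)
        nwk <- sub(ph[i], rep_str, nwk, fixed = TRUE)
      }
    }
    if (config$n_outgroups > 0) {
      # complex leaves stay at their depth; outgroup leaves hang straight
      # off the root at outgroup_divergence, making outgroup-to-complex
      # paths approximately outgroup_divergence + between_divergence
      og_ids <- sprintf("out%02d", seq_len(config$n_outgroups))
      og_nwk <- if (length(og_ids) == 1) {
        sprintf("%s:%g", og_ids, config$outgroup_divergence)
      } else {
        sprintf("%s:%g", rand_clade(og_ids, 0.1 * config$outgroup_divergence),
                0.9 * config$outgroup_divergence)
      }
      nwk <- sprintf("(%s:0,%s);", sub("; *$", "", nwk), og_nwk)
      labels <- bind_rows(labels, tibble(genome = og_ids, genomovar = "out"))
    }
    tree <- ape::read.tree(text = nwk)
    ntip <- length(tree$tip.label)
    tree$node.label <- paste0("n", (ntip + 1L):(ntip + tree$Nnode))
    list(tree = tree, labels = labels)
  })
}

#' Evolve gene content along a tree
#'
#' Families present at the root are lost independently along each branch with
#' probability `1 - exp(-loss_rate * t)` (loss is permanent within a lineage);
#' new families arise on each branch as a Poisson process with genome-wide
#' rate `gain_rate` per unit branch length, each gain founding a brand-new
#' family with no homology to existing ones. Realized event counts are
#' recorded per branch.
#'
#' @param tree Rooted `phylo` (as from [simulate_tree()]).
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `content` (named list: node label -> character vector of
#'   family ids), `events` (tibble: branch = child node label, parent, length,
#'   gains, losses), and `births` (tibble: family, branch, frac along branch).
#' @export
evolve_gene_content <- function(tree, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    labs <- node_labels(tree)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    eo <- edges_preorder(tree)
    root_fams <- sprintf("F%05d", seq_len(config$root_families))
    content <- vector("list", ntip + tree$Nnode)
    content[[root]] <- root_fams
    counter <- config$root_families
    ev <- vector("list", nrow(eo$edge))
    births <- list()
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chl <- eo$edge[e, 2]; t <- eo$length[e]
      present <- content[[par]]
      p_loss <- 1 - exp(-config$loss_rate * t)
      lost <- present[stats::runif(length(present)) < p_loss]
      n_new <- stats::rpois(1, config$gain_rate * t)
      new_fams <- character(0)
      if (n_new > 0) {
        new_fams <- sprintf("F%05d", counter + seq_len(n_new))
        counter <- counter + n_new
        births[[length(births) + 1L]] <- tibble(
          family = new_fams, branch = labs[chl],
          frac = stats::runif(n_new)
        )
      }
      content[[chl]] <- c(setdiff(present, lost), new_fams)
      ev[[e]] <- tibble(branch = labs[chl], parent = labs[par], length = t,
                        gains = n_new, losses = length(lost))
    }
    names(content) <- labs
    list(content = content,
         events = bind_rows(ev),
         births = if (length(births)) bind_rows(births) else
           tibble(family = character(), branch = character(), frac = numeric()))
  })
}

DNA_BASES <- c("A", "C", "G", "T")
SENSE_CODONS <- {
  all3 <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste0,
                collapse = "")
  setdiff(all3, c("TAA", "TAG", "TGA"))
}
# species-wide codon usage bias: strongly GC-rich third positions (overall
# GC ~63%, Pseudomonas-like) plus a fixed set of preferred codons. Shared
# across all families and genomes, it gives the complex a common
# tetranucleotide signature beyond the order-2 Markov background, as real
# codon usage does.
CODON_WEIGHTS <- local({
  gc3 <- ifelse(substr(SENSE_CODONS, 3, 3) %in% c("G", "C"), 9, 1)
  # fixed preferred-codon set, deterministic and uncorrelated with base
  # composition (drawn once from a frozen RNG stream)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(99)
  pref <- sample(c(1, 1, 1, 8), length(SENSE_CODONS), replace = TRUE)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  gc3 * pref
})

random_cds_int <- function(gene_length) {
  n_codon <- gene_length %/% 3L
  codons <- c("ATG", sample(SENSE_CODONS, n_codon - 2L, replace = TRUE,
                            prob = CODON_WEIGHTS),
              sample(c("TAA", "TAG", "TGA"), 1L))
  match(strsplit(paste0(codons, collapse = ""), "")[[1]], DNA_BASES)
}

# Jukes-Cantor transition sampling: each site substitutes with the closed-form
# change probability, uniformly to one of the three other bases.
mutate_int <- function(iv, t) {
  if (t <= 0) return(iv)
  p <- 0.75 * (1 - exp(-4 * t / 3))
  idx <- which(stats::runif(length(iv)) < p)
  if (length(idx)) {
    iv[idx] <- ((iv[idx] - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  }
  iv
}

int_to_dna <- function(iv) paste0(DNA_BASES[iv], collapse = "")

#' Evolve sequences and assemble annotated genomes
#'
#' Gives every family an ancestral coding sequence (ATG start, sense codons,
#' terminal stop) and mutates it along the tree under a Jukes-Cantor
#' substitution process. Each leaf genome is the concatenation of its gene
#' sequences in a per-genome random order, except the implanted marker
#' cluster which stays contiguous and ordered. Per-family strands are fixed
#' across genomes; minus-strand genes are reverse-complemented on the contig.
#'
#' @param tree Rooted `phylo`.
#' @param gc Result of [evolve_gene_content()].
#' @param config A [sim_config()].
#' @param seed Optional seed.
#' @return List with `genomes` (named list of `genome_record`),
#'   `marker_proteins` (ancestral marker `AAStringSet`, if implanted) and
#'   `cluster_status` tibble.
#' @export
evolve_sequences <- function(tree, gc, config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  assert_that(config$gene_length %% 3 == 0, "gene_length must be divisible by 3")
  with_seed(seed, {
    labs <- node_labels(tree)
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    eo <- edges_preorder(tree)
    markers <- if (config$implant_cluster) MARKER_GENES else character(0)

    # ancestral sequences for root families (+ markers)
    root_fams <- gc$content[[labs[root]]]
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[root]] <- lapply(
      stats::setNames(nm = c(root_fams, markers)),
      function(f) random_cds_int(config$gene_length)
    )
    births <- gc$births
    birth_seq <- lapply(stats::setNames(nm = births$family),
                        function(f) random_cds_int(config$gene_length))

    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chl <- eo$edge[e, 2]; t <- eo$length[e]
      keep <- c(gc$content[[labs[chl]]], markers)
      inherited <- intersect(keep, names(seqs[[par]]))
      s <- lapply(seqs[[par]][inherited], mutate_int, t = t)
      born_here <- births[births$branch == labs[chl], ]
      if (nrow(born_here)) {
        bs <- lapply(seq_len(nrow(born_here)), function(i) {
          mutate_int(birth_seq[[born_here$family[i]]],
                     t * (1 - born_here$frac[i]))
        })
        names(bs) <- born_here$family
        s <- c(s, bs[intersect(names(bs), keep)])
      }
      seqs[[chl]] <- s
    }
    names(seqs) <- labs

    all_fams <- unique(c(root_fams, births$family, markers))
    strand_of <- stats::setNames(sample(c("+", "-"), length(all_fams),
                                        replace = TRUE), all_fams)

    marker_prot <- NULL
    if (length(markers)) {
      mp <- Biostrings::AAStringSet(vapply(markers, function(m) {
        translate_cds(int_to_dna(seqs[[root]][[m]]))
      }, character(1)))
      names(mp) <- markers
      marker_prot <- mp
    }

    genomes <- list()
    cl_status <- list()
    for (tip in seq_len(ntip)) {
      gid <- tree$tip.label[tip]
      fams <- gc$content[[gid]]
      is_outgroup <- startsWith(gid, "out")
      drop_first <- config$implant_cluster && gid %in% config$drop_cluster_gene_in
      mk <- markers
      if (is_outgroup) mk <- character(0)   # cluster is a complex-specific trait
      if (drop_first) mk <- markers[-1]
      ord <- sample(fams)
      if (length(mk)) {
        # insert the marker block (ordered) at a random slot
        slot <- sample.int(length(ord) + 1L, 1L) - 1L
        ord <- append(ord, mk, after = slot)
      }
      genomes[[gid]] <- assemble_genome(gid, ord, seqs[[gid]], strand_of,
                                        config)
      if (config$implant_cluster) {
        cl_status[[gid]] <- tibble(
          genome = gid,
          status = if (is_outgroup) "absent" else
            if (drop_first) "partial" else "complete"
        )
      }
    }
    list(genomes = genomes,
         marker_proteins = marker_prot,
         cluster_status = if (length(cl_status)) bind_rows(cl_status) else
           tibble(genome = character(), status = character()))
  })
}

translate_cds <- function(dna) {
  # drop the terminal codon (ancestrally a stop, whatever it mutated to)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(dna, 1, nchar(dna) - 3))))
  gsub("\\*", "X", aa)           # substitution-created internal stops
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

assemble_genome <- function(gid, ordered_fams, seqs, strand_of, config) {
  n <- length(ordered_fams)
  # split gene list into contigs at gene boundaries
  nct <- max(1L, min(config$n_contigs, n))
  bounds <- sort(c(0L, if (nct > 1)
    sample(seq_len(n - 1L), nct - 1L) else integer(0), n))
  contig_of <- rep(seq_len(nct), diff(bounds))
  genes <- vector("list", n)
  contig_seq <- stats::setNames(rep("", nct), sprintf("%s_c%02d", gid, seq_len(nct)))
  pos <- rep(0L, nct)
  for (i in seq_len(n)) {
    fam <- ordered_fams[i]
    ct <- contig_of[i]
    sense <- int_to_dna(seqs[[fam]])
    strand <- strand_of[[fam]]
    on_contig <- if (strand == "+") sense else revcomp_chr(sense)
    genes[[i]] <- tibble(
      gene_id = sprintf("%s_%04d", gid, i),
      contig = names(contig_seq)[ct],
      start = pos[ct] + 1L,
      end = pos[ct] + nchar(on_contig),
      strand = strand,
      family = fam,
      rank = i
    )
    contig_seq[ct] <- paste0(contig_seq[ct], on_contig)
    pos[ct] <- pos[ct] + nchar(on_contig)
  }
  gene_tbl <- bind_rows(genes)
  prot <- vapply(seq_len(n), function(i)
    translate_cds(int_to_dna(seqs[[ordered_fams[i]]])), character(1))
  proteins <- Biostrings::AAStringSet(prot)
  names(proteins) <- gene_tbl$gene_id
  contigs <- Biostrings::DNAStringSet(contig_seq)
  genome_record(gid, contigs, gene_tbl, proteins)
}

#' Construct a genome record
#'
#' The unit of input for all genome-level operations: contig sequences, CDS
#' annotations (1-based inclusive coordinates) and the encoded proteins.
#'
#' @param id Genome identifier.
#' @param contigs Named `DNAStringSet`.
#' @param genes Tibble with columns gene_id, contig, start, end, strand,
#'   family (optional), rank.
#' @param proteins `AAStringSet` named by gene_id.
#' @return A `genome_record`.
#' @export
genome_record <- function(id, contigs, genes, proteins) {
  structure(list(id = id, contigs = contigs, genes = genes,
                 proteins = proteins),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d contig(s), %d bp, %d CDS\n",
              x$id, length(x$contigs), sum(Biostrings::width(x$contigs)),
              nrow(x$genes)))
  invisible(x)
}

#' Simulate a full synthetic species complex with its truth set
#'
#' Runs [simulate_tree()], [evolve_gene_content()] and [evolve_sequences()]
#' under sub-seeds derived deterministically from `config$seed`, and packages
#' the ground truth (tree, genomovar labels, pan matrix, per-branch events,
#' marker-cluster status) with the annotated genomes.
#'
#' @param config A [sim_config()].
#' @return A `complex_sim` list: `genomes`, `truth`, `config`.
#' @export
simulate_complex <- function(config = sim_config()) {
  seeds <- derive_seeds(config$seed, 3)
  st <- with_seed(seeds[[1]], simulate_tree(config))
  gc <- evolve_gene_content(st$tree, config, seed = seeds[[2]])
  sq <- evolve_sequences(st$tree, gc, config, seed = seeds[[3]])

  genomes <- sq$genomes
  fam_univ <- sort(unique(unlist(lapply(genomes, function(g) g$genes$family))))
  pm <- sapply(genomes, function(g) {
    tab <- table(g$genes$family)
    out <- stats::setNames(integer(length(fam_univ)), fam_univ)
    out[names(tab)] <- as.integer(tab)
    out
  })
  pan <- new_pan_matrix(pm)

  structure(list(
    genomes = genomes,
    truth = list(
      tree = st$tree,
      labels = st$labels,
      pan = pan,
      events = gc$events,
      cluster_status = sq$cluster_status,
      marker_proteins = sq$marker_proteins
    ),
    config = config
  ), class = "complex_sim")
}

#' @export
print.complex_sim <- function(x, ...) {
  cat(sprintf(
    "<complex_sim> %d genomes in %d genomovars; %d gene families; seed %d\n",
    length(x$genomes), x$config$n_genomovars, nrow(x$truth$pan),
    x$config$seed))
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

write_gff3 <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (ct in names(rec$contigs)) {
    writeLines(sprintf("##sequence-region %s 1 %d", ct,
                       Biostrings::width(rec$contigs[ct])), con)
  }
  g <- rec$genes
  fam <- if ("family" %in% names(g)) g$family else "."
  lines <- sprintf("%s\tgenomovar_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;Family=%s;Rank=%d",
                   g$contig, g$start, g$end, g$strand, g$gene_id, fam, g$rank)
  writeLines(lines, con)
}

read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  attr_get <- function(a, key) sub(sprintf(".*%s=([^;]*).*", key), "\\1", a)
  tibble(
    gene_id = attr_get(vapply(parts, `[`, "", 9), "ID"),
    contig = vapply(parts, `[`, "", 1),
    start = as.integer(vapply(parts, `[`, "", 4)),
    end = as.integer(vapply(parts, `[`, "", 5)),
    strand = vapply(parts, `[`, "", 7),
    family = attr_get(vapply(parts, `[`, "", 9), "Family"),
    rank = as.integer(attr_get(vapply(parts, `[`, "", 9), "Rank"))
  )
}

#' Write a simulated dataset to disk
#'
#' Emits per-genome nucleotide FASTA, protein FASTA and GFF3 (1-based
#' inclusive coordinates), the Newick truth tree, and TSV truth tables.
#' Re-reading with [read_dataset()] reproduces the dataset exactly.
#'
#' @param sim A `complex_sim`.
#' @param dir Output directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless TRUE.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "complex_sim"))
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    abort(sprintf("directory '%s' is non-empty; use overwrite = TRUE", dir))
  }
  gdir <- file.path(dir, "genomes"); tdir <- file.path(dir, "truth")
  dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (rec in sim$genomes) {
    Biostrings::writeXStringSet(rec$contigs, file.path(gdir, paste0(rec$id, ".fna")))
    Biostrings::writeXStringSet(rec$proteins, file.path(gdir, paste0(rec$id, ".faa")))
    write_gff3(rec, file.path(gdir, paste0(rec$id, ".gff3")))
  }
  ape::write.tree(sim$truth$tree, file.path(tdir, "tree.nwk"))
  utils::write.table(sim$truth$labels, file.path(tdir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pan_matrix(sim$truth$pan, file.path(tdir, "pan_matrix.tsv"))
  utils::write.table(sim$truth$events, file.path(tdir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$cluster_status, file.path(tdir, "cluster_status.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$marker_proteins)) {
    Biostrings::writeXStringSet(sim$truth$marker_proteins,
                                file.path(tdir, "marker_proteins.faa"))
  }
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return A `complex_sim` list (genomes + truth + config).
#' @export
read_dataset <- function(dir) {
  gdir <- file.path(dir, "genomes"); tdir <- file.path(dir, "truth")
  ids <- sub("\\.fna$", "", list.files(gdir, pattern = "\\.fna$"))
  genomes <- lapply(stats::setNames(nm = ids), function(id) {
    contigs <- Biostrings::readDNAStringSet(file.path(gdir, paste0(id, ".fna")))
    names(contigs) <- sub(" .*", "", names(contigs))
    proteins <- Biostrings::readAAStringSet(file.path(gdir, paste0(id, ".faa")))
    names(proteins) <- sub(" .*", "", names(proteins))
    genes <- read_gff3(file.path(gdir, paste0(id, ".gff3")))
    genome_record(id, contigs, genes, proteins)
  })
  read_tsv0 <- function(p) as_tibble(utils::read.table(
    p, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
    colClasses = NA, check.names = FALSE))
  mp_path <- file.path(tdir, "marker_proteins.faa")
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  structure(list(
    genomes = genomes,
    truth = list(
      tree = ape::read.tree(file.path(tdir, "tree.nwk")),
      labels = read_tsv0(file.path(tdir, "labels.tsv")),
      pan = read_pan_matrix(file.path(tdir, "pan_matrix.tsv")),
      events = read_tsv0(file.path(tdir, "events.tsv")),
      cluster_status = if (file.size(file.path(tdir, "cluster_status.tsv")) > 25)
        read_tsv0(file.path(tdir, "cluster_status.tsv")) else
          tibble(genome = character(), status = character()),
      marker_proteins = if (file.exists(mp_path))
        Biostrings::readAAStringSet(mp_path) else NULL
    ),
    config = do.call(sim_config, cfg)
  ), class = "complex_sim")
}
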