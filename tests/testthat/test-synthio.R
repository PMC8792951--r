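test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_genomovars = 0), "n_genomovars")
  expect_error(sim_config(gain_rate = -1), "rates")
  expect_error(sim_config(gene_length = 100), "divisible")
  expect_error(sim_config(within_divergence = 0.1,
                          between_divergence = 0.05), "exceed")
  expect_error(sim_config(n_outgroups = 1, outgroup_divergence = 0.05),
               "outgroup_divergence")
})

test_that("simulated trees have the genomovar clade structure", {
  # minimal case: one genomovar, two genomes
  st <- simulate_tree(sim_config(n_genomovars = 1, genomes_per_genomovar = 2))
  expect_equal(ape::Ntip(st$tree), 2)
  expect_equal(unique(st$labels$genomovar), "gv01")

  # determinism: identical Newick for identical config
  cfg <- sim_config(n_genomovars = 3, genomes_per_genomovar = 4, seed = 7)
  nwk1 <- ape::write.tree(simulate_tree(cfg)$tree)
  nwk2 <- ape::write.tree(simulate_tree(cfg)$tree)
  expect_identical(nwk1, nwk2)

  # separation: every between-clade path longer than every within-clade
  # path, by exhaustive enumeration of all leaf pairs
  cfg <- sim_config(n_genomovars = 2, genomes_per_genomovar = 3,
                    within_divergence = 0.01, between_divergence = 0.08,
                    seed = 3)
  st <- simulate_tree(cfg)
  D <- ape::cophenetic.phylo(st$tree)
  gv <- setNames(st$labels$genomovar, st$labels$genome)
  same <- outer(gv[rownames(D)], gv[colnames(D)], "==")
  within_max <- max(D[same & upper.tri(D)])
  between_min <- min(D[!same & upper.tri(D)])
  expect_gt(between_min, within_max)
  expect_gte(between_min, 2 * cfg$between_divergence - 1e-9)
  expect_equal(within_max, 2 * cfg$within_divergence, tolerance = 1e-6)
})

test_that("gene content evolves by the gain-loss process", {
  cfg0 <- sim_config(gain_rate = 0, loss_rate = 0, root_families = 50,
                     n_genomovars = 2, genomes_per_genomovar = 2, seed = 5)
  st <- simulate_tree(cfg0)
  gc <- evolve_gene_content(st$tree, cfg0)
  root_set <- sort(sprintf("F%05d", 1:50))
  for (tip in st$tree$tip.label) {
    expect_identical(sort(gc$content[[tip]]), root_set)
  }
  expect_true(all(gc$events$gains == 0 & gc$events$losses == 0))

  # gain-only: family count non-decreasing from root to every leaf
  cfg_g <- sim_config(gain_rate = 200, loss_rate = 0, root_families = 50,
                      n_genomovars = 2, genomes_per_genomovar = 3, seed = 6)
  st <- simulate_tree(cfg_g)
  gc <- evolve_gene_content(st$tree, cfg_g)
  labs <- c(st$tree$tip.label,
            paste0("n", (ape::Ntip(st$tree) + 1):(ape::Ntip(st$tree) + st$tree$Nnode)))
  for (e in seq_len(nrow(gc$events))) {
    expect_gte(length(gc$content[[gc$events$branch[e]]]),
               length(gc$content[[gc$events$parent[e]]]))
  }
})

test_that("per-branch loss frequency matches the two-state closed form", {
  # 10,000 families on a single branch pair of known length
  t_len <- 0.5; l_rate <- 1.2
  cfg <- sim_config(n_genomovars = 1, genomes_per_genomovar = 2,
                    root_families = 10000, gain_rate = 0, loss_rate = l_rate,
                    within_divergence = t_len, seed = 11)
  st <- simulate_tree(cfg)
  gc <- evolve_gene_content(st$tree, cfg)
  p_expect <- 1 - exp(-l_rate * t_len)
  mc_se <- sqrt(p_expect * (1 - p_expect) / 10000)
  for (e in which(gc$events$length > 0)) {
    p_obs <- gc$events$losses[e] / 10000
    expect_lt(abs(p_obs - p_expect), 3 * mc_se + 1e-9)
  }
})

test_that("sequence divergence follows the Jukes-Cantor expectation", {
  # zero divergence: all orthologs identical, ANI exactly 100
  cfg0 <- sim_config(n_genomovars = 1, genomes_per_genomovar = 2,
                     root_families = 40, gain_rate = 0, loss_rate = 0,
                     within_divergence = 0, seed = 21)
  sim0 <- simulate_complex(cfg0)
  g1 <- sim0$genomes[[1]]; g2 <- sim0$genomes[[2]]
  seq_by_fam <- function(g) {
    sapply(stats::setNames(nm = g$genes$family), function(fam) {
      row <- g$genes[g$genes$family == fam, ]
      s <- as.character(Biostrings::subseq(g$contigs[[row$contig]],
                                           row$start, row$end))
      if (row$strand == "-") s <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(s)))
      s
    })
  }
  f1 <- seq_by_fam(g1)
  expect_identical(f1, seq_by_fam(g2)[names(f1)])   # orthologs identical
  # gene order is still permuted between the genomes, so local alignments
  # may absorb a base or two across gene junctions; identity stays
  # essentially exact (the strictly identical-content case is covered by
  # the self-comparison fixed point)
  expect_equal(fragment_ani(g1, g2)$ani_percent, 100, tolerance = 2e-4)

  # known path length: column-wise mismatch counting on ortholog pairs
  div <- 0.025  # per-lineage, so leaf-to-leaf path = 0.05
  cfg <- sim_config(n_genomovars = 1, genomes_per_genomovar = 2,
                    root_families = 60, gain_rate = 0, loss_rate = 0,
                    within_divergence = div, seed = 22)
  sim <- simulate_complex(cfg)
  g1 <- sim$genomes[[1]]; g2 <- sim$genomes[[2]]
  seq_of <- function(g, fam) {
    row <- g$genes[g$genes$family == fam, ]
    s <- as.character(Biostrings::subseq(g$contigs[[row$contig]],
                                         row$start, row$end))
    if (row$strand == "-") s <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    s
  }
  mm <- 0L; tot <- 0L
  for (fam in sprintf("F%05d", 1:60)) {
    a <- charToRaw(seq_of(g1, fam)); b <- charToRaw(seq_of(g2, fam))
    mm <- mm + sum(a != b); tot <- tot + length(a)
  }
  p_exp <- 0.75 * (1 - exp(-4 * (2 * div) / 3))
  expect_lt(abs(mm / tot - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / tot))
})

test_that("the implanted marker cluster is contiguous, ordered, and droppable", {
  sim <- fixture_sim()
  marker <- c("ectA", "ectB", "ectC", "ectD", "ask_ect")
  for (g in sim$genomes) {
    fams <- g$genes$family[order(g$genes$rank)]
    present <- intersect(marker, fams)
    exp_present <- if (g$id == "gv02_s03") marker[-1] else marker
    expect_identical(present[order(match(present, marker))], exp_present)
    pos <- match(exp_present, fams)
    expect_identical(pos, seq(min(pos), length.out = length(pos)))
  }
  st <- sim$truth$cluster_status
  expect_identical(st$status[st$genome == "gv02_s03"], "partial")
  expect_true(all(st$status[st$genome != "gv02_s03"] == "complete"))
})

test_that("datasets round-trip through FASTA/GFF3/TSV exactly", {
  sim <- simulate_complex(sim_config(
    n_genomovars = 2, genomes_per_genomovar = 2, root_families = 30,
    gain_rate = 50, loss_rate = 1, implant_cluster = TRUE, seed = 31))
  dir <- withr::local_tempdir()
  write_dataset(sim, file.path(dir, "ds"))
  expect_error(write_dataset(sim, file.path(dir, "ds")), "overwrite")
  back <- read_dataset(file.path(dir, "ds"))
  for (id in names(sim$genomes)) {
    expect_identical(as.character(back$genomes[[id]]$contigs),
                     as.character(sim$genomes[[id]]$contigs))
    expect_identical(as.character(back$genomes[[id]]$proteins),
                     as.character(sim$genomes[[id]]$proteins))
    expect_equal(as.data.frame(back$genomes[[id]]$genes),
                 as.data.frame(sim$genomes[[id]]$genes))
  }
  expect_identical(unclass(back$truth$pan), unclass(sim$truth$pan))
  expect_equal(as.data.frame(back$truth$labels),
               as.data.frame(sim$truth$labels))
  expect_identical(ape::write.tree(back$truth$tree),
                   ape::write.tree(sim$truth$tree))

  # GFF3 convention: 1-based inclusive; first CDS starts at 1
  gff <- readLines(list.files(file.path(dir, "ds", "genomes"),
                              pattern = "gff3$", full.names = TRUE)[1])
  first <- strsplit(gff[!startsWith(gff, "#")][1], "\t")[[1]]
  expect_identical(first[4], "1")

  # protein FASTA record count equals the genome's pan-matrix column sum
  for (id in names(sim$genomes)) {
    expect_equal(length(back$genomes[[id]]$proteins),
                 sum(unclass(sim$truth$pan)[, id]))
  }
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(n_genomovars = 2, genomes_per_genomovar = 2,
                    root_families = 25, gain_rate = 40, loss_rate = 1,
                    implant_cluster = TRUE, seed = 77)
  s1 <- simulate_complex(cfg); s2 <- simulate_complex(cfg)
  expect_identical(
    lapply(s1$genomes, function(g) as.character(g$contigs)),
    lapply(s2$genomes, function(g) as.character(g$contigs)))
  expect_identical(ape::write.tree(s1$truth$tree),
                   ape::write.tree(s2$truth$tree))
  expect_identical(unclass(s1$truth$pan), unclass(s2$truth$pan))
})
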