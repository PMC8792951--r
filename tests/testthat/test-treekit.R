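test_that("neighbor-joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- nj_tree(new_dist_matrix(d, "test"))
  # three-point formulas: x = (dab + dac - dbc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl["a"]), (5 + 9 - 8) / 2)
  expect_equal(unname(bl["b"]), (5 + 8 - 9) / 2)
  expect_equal(unname(bl["c"]), (9 + 8 - 5) / 2)
  expect_error(nj_tree(new_dist_matrix(d[1:2, 1:2], "t")), "at least 3")
})

test_that("NJ recovers additive matrices exactly", {
  # known trees up to 8 taxa: topology and branch lengths from the
  # cophenetic (additive) matrix
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    for (n in c(5, 8)) {
      true <- ape::rtree(n)
      true$edge.length <- true$edge.length + 0.1
      D <- ape::cophenetic.phylo(true)
      D <- D[sort(rownames(D)), sort(colnames(D))]
      est <- nj_tree(new_dist_matrix(D, "additive"))
      expect_equal(ape::dist.topo(ape::unroot(true), est), 0,
                   ignore_attr = TRUE)
      expect_equal(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] - D)),
                   0, tolerance = 1e-8)
    }
  }
})

test_that("concatenated core distances count differing sites", {
  # identical sequences -> zero matrix
  g <- setNames(vapply(1:4, function(i) random_dna(300, seed = 40 + i),
                       character(1)), paste0("F0000", 1:4))
  r1 <- make_record("a", g); r2 <- make_record("b", g)
  d0 <- concat_core_distance(list(a = r1, b = r2), names(g))
  expect_true(all(unclass(d0) == 0))

  # exactly 12 differing sites out of 1,200 -> distance 0.01
  g2 <- g
  v <- strsplit(g2[[1]], "")[[1]]
  set.seed(7)
  idx <- sample(300, 12)
  for (i in idx) v[i] <- setdiff(c("A", "C", "G", "T"), v[i])[1]
  g2[[1]] <- paste(v, collapse = "")
  r3 <- make_record("b", g2)
  d1 <- concat_core_distance(list(a = r1, b = r3), names(g))
  expect_equal(unclass(d1)["a", "b"], 12 / 1200, tolerance = 1e-12)

  expect_error(concat_core_distance(list(a = r1, b = r2), character(0)),
               "core")
})

test_that("Kendall-Colijn distance matches hand enumeration", {
  t1 <- ape::read.tree(text = "(((a:1,b:1):1,c:2):1,d:3);")   # caterpillar
  t2 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")   # balanced
  expect_equal(kc_distance(t1, t1), 0)
  expect_gt(kc_distance(t1, t2), 0)

  # hand-enumerated root-to-MRCA edge counts, pairs in sorted label order:
  # (a,b) (a,c) (a,d) (b,c) (b,d) (c,d)
  v1 <- c(2, 1, 0, 1, 0, 0)
  v2 <- c(1, 0, 0, 0, 0, 1)
  expect_equal(kc_distance(t1, t2), sqrt(sum((v1 - v2)^2)))

  expect_error(kc_distance(t1, ape::read.tree(text = "((a:1,b:1):1,(c:1,x:1):1);")),
               "leaf set")
})

test_that("Kendall-Colijn is a metric on enumerated rooted topologies", {
  set.seed(14)
  trees <- replicate(6, ape::rcoal(5, tip.label = letters[1:5]),
                     simplify = FALSE)
  d <- outer(seq_along(trees), seq_along(trees),
             Vectorize(function(i, j) kc_distance(trees[[i]], trees[[j]])))
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("the random-tree null test is calibrated and rejects sanely", {
  labs <- paste0("t", 1:8)
  set.seed(21)
  ref <- ape::rcoal(8, tip.label = labs)
  # query identical to reference: strongly significant
  res <- kc_null_test(ref, ref, n_random = 300, seed = 1)
  expect_equal(res$d_obs, 0)
  expect_lt(res$p_value, 0.05)
  expect_error(kc_null_test(ref, ref, n_random = 50), "unstable")

  # random queries under the null: rejection rate near alpha
  rej <- vapply(1:100, function(i) {
    q <- ape::rcoal(8, tip.label = sample(labs))
    kc_null_test(q, ref, n_random = 150, seed = 1000 + i)$p_value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("genomovar delineation is a thresholded transitive closure", {
  # all high ANI -> one genomovar
  labs <- paste0("g", 1:4)
  ani <- matrix(99, 4, 4, dimnames = list(labs, labs)); diag(ani) <- 100
  ddh <- matrix(90, 4, 4, dimnames = list(labs, labs)); diag(ddh) <- 100
  a1 <- delineate_genomovars(new_dist_matrix(ani, "ani"),
                             new_dist_matrix(ddh, "ddh"))
  expect_equal(length(unique(a1$genomovar)), 1)

  # the borderline pair: ANI 94.89 / dDDH 59.9 joins under default
  # cutoffs and splits at 95.0 / 60.0
  labs2 <- c("DCP_Ps1", "JL972")
  ani2 <- matrix(c(100, 94.89, 94.89, 100), 2, dimnames = list(labs2, labs2))
  ddh2 <- matrix(c(100, 59.9, 59.9, 100), 2, dimnames = list(labs2, labs2))
  a_def <- delineate_genomovars(new_dist_matrix(ani2, "ani"),
                                new_dist_matrix(ddh2, "ddh"))
  expect_equal(length(unique(a_def$genomovar)), 1)
  a_hi <- delineate_genomovars(new_dist_matrix(ani2, "ani"),
                               new_dist_matrix(ddh2, "ddh"),
                               ani_t = 95.0, ddh_t = 60.0)
  expect_equal(length(unique(a_hi$genomovar)), 2)

  # thresholds above all observed values -> N singletons
  a_max <- delineate_genomovars(new_dist_matrix(ani, "ani"),
                                new_dist_matrix(ddh, "ddh"),
                                ani_t = 100.5, ddh_t = 100.5)
  expect_equal(length(unique(a_max$genomovar)), 4)

  # random threshold graph: components equal an independent transitive
  # closure by boolean matrix powering
  set.seed(31)
  n <- 12; labs3 <- sprintf("r%02d", 1:n)
  av <- matrix(runif(n * n, 90, 99), n, n, dimnames = list(labs3, labs3))
  av[lower.tri(av)] <- t(av)[lower.tri(av)]; diag(av) <- 100
  dv <- matrix(runif(n * n, 50, 70), n, n, dimnames = list(labs3, labs3))
  dv[lower.tri(dv)] <- t(dv)[lower.tri(dv)]; diag(dv) <- 100
  asg <- delineate_genomovars(new_dist_matrix(av, "ani"),
                              new_dist_matrix(dv, "ddh"),
                              ani_t = 95, ddh_t = 60)
  adj <- (av >= 95 & dv >= 60); diag(adj) <- TRUE
  reach <- adj
  for (i in 1:n) reach <- (reach %*% adj) > 0   # closure oracle
  oracle <- apply(reach, 1, function(r) paste(which(r), collapse = ","))
  expect_equal(adjusted_rand(asg$genomovar[match(labs3, asg$genome)], oracle), 1)
})

test_that("membership screening combines the ANI prefilter with both trees", {
  sim <- fixture_membership_sim()
  dists <- fixture_membership_dists()
  fams <- fx("mfams", cluster_homologs(sim$genomes))
  pan <- pan_matrix(fams, names(sim$genomes))
  core <- fx("mcore", concat_core_distance(sim$genomes, fams,
                                           core = single_copy_core(pan)))
  refs <- c("gv01_s01", "gv02_s01")
  out <- membership_screen(dists$ani, core, references = refs,
                           outgroup = c("out01", "out02"))
  members <- out$genome[out$member]
  complex_ids <- sim$truth$labels$genome[sim$truth$labels$genomovar != "out"]
  expect_setequal(members, complex_ids)
  og <- out[out$genome %in% c("out01", "out02"), ]
  expect_true(all(!og$member))
  expect_true(all(og$max_ref_ani < 80 | !og$in_ani_clade | !og$in_core_clade))
  # candidate identical to a reference is always a member
  expect_true(out$member[out$genome == "gv01_s01"])
})

test_that("taxonomy reports flag misidentified and novel genomes", {
  asg <- structure(
    tibble(genome = c("a1", "a2", "b1", "b2", "c1"),
           genomovar = c("gv01", "gv01", "gv02", "gv02", "gv03")),
    class = c("genomovar_assignment", "tbl_df", "tbl", "data.frame"))
  refs <- c(a1 = "P. alpha", b1 = "P. beta")

  # all declared names match -> all consistent
  ok <- taxonomy_report(asg, c(a1 = "P. alpha", a2 = "P. alpha",
                               b1 = "P. beta", b2 = "P. beta", c1 = "sp."),
                        refs)
  expect_equal(sum(ok$verdict == "misidentified"), 0)
  expect_identical(ok$verdict[ok$genome == "c1"], "novel_genomovar")

  # one planted wrong label -> exactly that genome flagged
  bad <- taxonomy_report(asg, c(a1 = "P. alpha", a2 = "P. beta",
                                b1 = "P. beta", b2 = "sp.", c1 = "sp."),
                         refs)
  expect_identical(bad$genome[bad$verdict == "misidentified"], "a2")
  expect_identical(bad$verdict[bad$genome == "b2"], "newly_assigned")
  smry <- attr(bad, "summary")
  expect_equal(sum(smry$n), 5)
})

test_that("genome statistics and the GC group test behave", {
  expect_equal(genome_stats(list(x = make_record("x", c(F1 = "ATGC"))))$gc_percent,
               50)
  set.seed(41)
  s <- random_dna(10000)
  gs <- genome_stats(list(g = make_record("g", c(F1 = s))))
  expect_equal(gs$gc_percent,
               100 * sum(strsplit(s, "")[[1]] %in% c("G", "C")) / 10000)

  # two groups drawn from distinct GC generators: Welch test rejects
  set.seed(42)
  lo <- lapply(1:4, function(i) make_record(paste0("lo", i),
                                            c(F1 = random_dna(20000, gc = 0.55))))
  hi <- lapply(1:4, function(i) make_record(paste0("hi", i),
                                            c(F1 = random_dna(20000, gc = 0.63))))
  names(lo) <- paste0("lo", 1:4); names(hi) <- paste0("hi", 1:4)
  groups <- setNames(rep(c("low", "high"), each = 4), c(names(lo), names(hi)))
  gs <- genome_stats(c(lo, hi), groups = groups)
  expect_lt(attr(gs, "gc_test")$p.value, 0.01)
})
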