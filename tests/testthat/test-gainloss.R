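test_that("pruning likelihood equals exhaustive enumeration on small trees", {
  for (nwk in c("((a:0.3,b:0.5):0.2,c:0.7);",
                "(((a:0.2,b:0.2):0.2,(c:0.3,d:0.1):0.4):0.1,e:0.6);")) {
    tree <- ape::read.tree(text = nwk)
    tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    set.seed(8)
    X <- matrix(rbinom(5 * ape::Ntip(tree), 1, 0.6), 5,
                dimnames = list(paste0("f", 1:5), tree$tip.label))
    pan <- new_pan_matrix(X)
    model <- structure(list(gain = 0.7, loss = 1.3, root_prior = 0.4,
                            posterior_threshold = 0.5),
                       class = "gainloss_model")
    ll_prune <- genomovar:::inside_pass(
      genomovar:::tree_struct(tree, colnames(pan)),
      genomovar:::presence_view(pan), 0.7, 1.3, 0.4)$loglik
    ll_enum <- enum_loglik(tree, X, 0.7, 1.3, 0.4)
    expect_lt(abs(ll_prune - ll_enum), 1e-10)
  }
})

test_that("rates are recovered from matched-model simulations", {
  # frozen content: fitted rates collapse to the lower boundary
  tree <- ape::rcoal(8)
  X <- matrix(1L, 50, 8, dimnames = list(paste0("f", 1:50), tree$tip.label))
  expect_warning(m0 <- fit_gainloss(new_pan_matrix(X), tree), "boundary")
  expect_lt(m0$loss, 1e-3)

  # 20-leaf, 300-family simulation at known rates
  set.seed(17)
  tree20 <- ape::rcoal(20)
  tree20$edge.length <- tree20$edge.length / max(ape::node.depth.edgelength(tree20)) * 3
  pan <- simulate_profiles(tree20, gain = 0.5, loss = 1.0,
                           n_families = 300, seed = 18)
  fit <- fit_gainloss(pan, tree20)
  expect_lt(abs(fit$gain - 0.5) / 0.5, 0.2)
  expect_lt(abs(fit$loss - 1.0) / 1.0, 0.2)
})

test_that("branch posteriors localize events and respect bounds", {
  tree <- ape::read.tree(text = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);")
  model <- structure(list(gain = 0.4, loss = 0.8, root_prior = 0.3,
                          posterior_threshold = 0.5),
                     class = "gainloss_model")

  # family present only in leaf a: gain posterior maximal on a's branch,
  # checked against exhaustive enumeration of the joint
  X <- matrix(c(1, 0, 0, 0), 1, 4,
              dimnames = list("f1", c("a", "b", "c", "d")))
  post <- branch_posteriors(new_pan_matrix(X), tree, model)
  ga <- post$gain[, "f1"]
  expect_equal(names(which.max(ga)), "a")

  # enumeration oracle for P(parent=0, child=1 | data) on a's branch
  tr <- ape::reorder.phylo(tree, "postorder")
  trans <- function(a, b, t) {
    s <- model$gain + model$loss; e <- exp(-s * t)
    m <- matrix(c((model$loss + model$gain * e) / s,
                  model$loss * (1 - e) / s,
                  model$gain * (1 - e) / s,
                  (model$gain + model$loss * e) / s), 2, 2)
    m[a + 1, b + 1]
  }
  obs <- X[1, tr$tip.label]
  num <- 0; den <- 0
  n_int <- tr$Nnode
  a_tip <- which(tr$tip.label == "a")
  a_edge <- which(tr$edge[, 2] == a_tip)
  a_parent <- tr$edge[a_edge, 1]
  for (code in 0:(2^n_int - 1)) {
    states <- c(obs, as.integer(intToBits(code))[1:n_int])
    p <- if (states[5] == 1) model$root_prior else 1 - model$root_prior
    for (e in seq_len(nrow(tr$edge))) {
      p <- p * trans(states[tr$edge[e, 1]], states[tr$edge[e, 2]],
                     tr$edge.length[e])
    }
    den <- den + p
    if (states[a_parent] == 0 && states[a_tip] == 1) num <- num + p
  }
  expect_equal(unname(post$gain["a", "f1"]), num / den, tolerance = 1e-10)

  # bounds and threshold exclusivity over random data
  set.seed(12)
  X2 <- matrix(rbinom(40, 1, 0.5), 10, 4,
               dimnames = list(paste0("f", 1:10), c("a", "b", "c", "d")))
  p2 <- branch_posteriors(new_pan_matrix(X2), tree, model)
  expect_true(all(p2$gain >= 0 & p2$gain <= 1))
  expect_true(all(p2$loss >= 0 & p2$loss <= 1))
  expect_false(any(p2$gain > 0.5 & p2$loss > 0.5))

  # all-present family under tiny loss: loss posteriors near zero
  model_l0 <- structure(list(gain = 0.4, loss = 1e-6, root_prior = 0.5,
                             posterior_threshold = 0.5),
                        class = "gainloss_model")
  X3 <- matrix(1, 1, 4, dimnames = list("f1", c("a", "b", "c", "d")))
  p3 <- branch_posteriors(new_pan_matrix(X3), tree, model_l0)
  expect_lt(max(p3$loss), 1e-4)
})

test_that("likely events threshold, total and attribute correctly", {
  tree <- ape::read.tree(text = "((a:0.2,b:0.2):0.2,(c:0.2,d:0.2):0.2);")
  set.seed(23)
  X <- matrix(rbinom(200, 1, 0.5), 50, 4,
              dimnames = list(paste0("f", 1:50), c("a", "b", "c", "d")))
  pan <- new_pan_matrix(X)
  model <- structure(list(gain = 0.6, loss = 1.0, root_prior = 0.4,
                          posterior_threshold = 0.5),
                     class = "gainloss_model")
  post <- branch_posteriors(pan, tree, model)
  ev <- likely_events(post)
  # totals equal a brute-force count over the posterior matrices
  expect_equal(attr(ev, "totals")$gains, sum(post$gain > 0.5))
  expect_equal(attr(ev, "totals")$losses, sum(post$loss > 0.5))
  expect_equal(ev$likely_gains, unname(rowSums(post$gain > 0.5)))

  # all posteriors below threshold -> zero likely events
  ev99 <- likely_events(post, threshold = 0.999999)
  expect_equal(attr(ev99, "totals")$gains, 0)

  # per-category attribution sums to the totals
  cats <- categorize_pan(pan)
  evc <- likely_events(post, categories = cats)
  pc <- attr(evc, "per_category")
  expect_equal(sum(pc$gains), attr(evc, "totals")$gains)
})

test_that("gain-only histories infer near-zero losses, mostly terminal gains", {
  set.seed(27)
  tree <- ape::rcoal(10)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) * 3
  pan <- simulate_profiles(tree, gain = 0.8, loss = 0, n_families = 250,
                           root_prior = 0.15, seed = 28)
  expect_warning(fit <- fit_gainloss(pan, tree), "boundary")
  post <- branch_posteriors(pan, tree, fit)
  ev <- likely_events(post)
  expect_equal(attr(ev, "totals")$losses, 0)
  expect_gt(attr(ev, "totals")$gains, 0)
})

test_that("Wagner parsimony matches exhaustive minimal-cost search", {
  # family in all leaves: root present, zero events
  tree6 <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):2);")
  X_all <- matrix(1, 1, 6, dimnames = list("f1", tree6$tip.label))
  w <- wagner_parsimony(new_pan_matrix(X_all), tree6)
  expect_true(all(w$gains == 0 & w$losses == 0))

  # single-leaf family with gain penalty 2: one terminal gain beats losses
  X_one <- matrix(as.integer(tree6$tip.label == "c"), 1, 6,
                  dimnames = list("f1", tree6$tip.label))
  w1 <- wagner_parsimony(new_pan_matrix(X_one), tree6, gain_penalty = 2)
  expect_equal(sum(w1$gains), 1)
  expect_equal(sum(w1$losses), 0)
  expect_equal(w1$gains[w1$branch == "c"], 1)

  # exhaustive oracle over all ancestral state assignments, random data
  set.seed(33)
  for (rep in 1:3) {
    X <- matrix(rbinom(6, 1, 0.5), 1, 6, dimnames = list("f", tree6$tip.label))
    w <- wagner_parsimony(new_pan_matrix(X), tree6, gain_penalty = 2)
    cost_pkg <- 2 * sum(w$gains) + sum(w$losses)
    expect_equal(cost_pkg, wagner_cost_oracle(tree6, X[1, ], 2))
  }
})

test_that("parsimony and ML likely-events agree on low-rate simulations", {
  set.seed(35)
  tree <- ape::rcoal(12)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) * 3
  pan <- simulate_profiles(tree, gain = 0.3, loss = 0.4, n_families = 200,
                           seed = 36)
  fit <- fit_gainloss(pan, tree)
  post <- branch_posteriors(pan, tree, fit)
  wp <- wagner_parsimony(pan, tree)
  # per family and branch, the thresholded ML call vs the parsimony call
  ge <- attr(wp, "gain_events")[rownames(post$gain), colnames(post$gain)]
  le <- attr(wp, "loss_events")[rownames(post$loss), colnames(post$loss)]
  agree <- mean((post$gain > 0.5) == ge & (post$loss > 0.5) == le)
  expect_gte(agree, 0.9)
})

test_that("event totals are invariant to leaf-order permutation", {
  set.seed(39)
  tree <- ape::rcoal(8)
  pan <- simulate_profiles(tree, gain = 0.5, loss = 0.8, n_families = 120,
                           seed = 40)
  model <- structure(list(gain = 0.5, loss = 0.8, root_prior = 0.4,
                          posterior_threshold = 0.5),
                     class = "gainloss_model")
  ev1 <- likely_events(branch_posteriors(pan, tree, model))
  perm <- new_pan_matrix(unclass(pan)[, sample(colnames(pan))])
  ev2 <- likely_events(branch_posteriors(perm, tree, model))
  expect_equal(attr(ev1, "totals"), attr(ev2, "totals"))
})
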