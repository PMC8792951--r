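# Two-state (presence/absence) Markov model of gene-family gain and loss on
# a rooted tree. States: 1 = absent, 2 = present. Family copy numbers are
# collapsed to presence; gains are 0->1 transitions at rate `gain`, losses
# 1->0 at rate `loss`, per unit branch length.

trans_mat <- function(gain, loss, t) {
  s <- gain + loss
  if (s <= 0 || t <= 0) return(diag(2))
  e <- exp(-s * t)
  matrix(c((loss + gain * e) / s, loss * (1 - e) / s,
           gain * (1 - e) / s, (gain + loss * e) / s),
         2, 2)  # [from, to], column-major: [1,1],[2,1],[1,2],[2,2]
}

# postorder edge list and tip index map for a rooted tree
tree_struct <- function(tree, genomes) {
  assert_that(ape::is.rooted(tree), "tree must be rooted")
  assert_that(setequal(tree$tip.label, genomes),
              "tree leaves must match genome labels")
  tr <- ape::reorder.phylo(tree, "postorder")
  list(tree = tr, edge = tr$edge, len = tr$edge.length,
       ntip = length(tr$tip.label), root = length(tr$tip.label) + 1L,
       labels = node_labels(tr))
}

# inside (pruning) pass; returns per-node 2 x F conditional likelihoods and
# the total log-likelihood
inside_pass <- function(st, X, gain, loss, root_prior) {
  nn <- st$ntip + st$tree$Nnode
  Fn <- nrow(X)
  L <- vector("list", nn)
  for (tip in seq_len(st$ntip)) {
    x <- X[, st$tree$tip.label[tip]]
    L[[tip]] <- rbind(as.numeric(!x), as.numeric(x))
  }
  for (node in (st$ntip + 1L):nn) L[[node]] <- matrix(1, 2, Fn)
  Pm <- vector("list", nrow(st$edge))
  for (e in seq_len(nrow(st$edge))) {
    Pm[[e]] <- trans_mat(gain, loss, st$len[e])
    par <- st$edge[e, 1]; chl <- st$edge[e, 2]
    L[[par]] <- L[[par]] * (Pm[[e]] %*% L[[chl]])
  }
  prior <- c(1 - root_prior, root_prior)
  lik <- colSums(prior * L[[st$root]])
  list(L = L, P = Pm, loglik = sum(log(pmax(lik, 1e-300))), lik = lik,
       prior = prior)
}

#' Fit gain/loss rates by maximum likelihood
#'
#' Fits the two-state Markov model (gain rate, loss rate, root presence
#' prior) to a presence/absence pan matrix on a rooted tree by Felsenstein
#' pruning, optimized by coordinate-wise golden-section search over up to
#' `rounds` rounds.
#'
#' @param pan A `pan_matrix` (copy counts are collapsed to presence).
#' @param tree Rooted `phylo` whose leaves are the pan matrix genomes.
#' @param rounds Maximum optimization rounds (default 100).
#' @param root_prior "estimate" (default) or a fixed probability in (0, 1).
#' @param posterior_threshold Stored threshold for "likely events".
#' @return A `gainloss_model`: gain, loss, root_prior, loglik, rounds_used,
#'   posterior_threshold. All-present matrices drive the loss rate to its
#'   lower bound with a warning, not an error.
#' @export
fit_gainloss <- function(pan, tree, rounds = 100, root_prior = "estimate",
                         posterior_threshold = 0.5) {
  X <- presence_view(pan)
  st <- tree_struct(tree, colnames(pan))
  estimate_prior <- identical(root_prior, "estimate")
  p1 <- if (estimate_prior) mean(X) else root_prior
  ll_of <- function(g, l, p) inside_pass(st, X, g, l, p)$loglik
  g <- 0.5; l <- 0.5
  lo <- 1e-6; hi <- 1e3
  last <- -Inf
  used <- 0L
  for (r in seq_len(rounds)) {
    used <- r
    g <- stats::optimize(function(v) ll_of(exp(v), l, p1),
                         c(log(lo), log(hi)), maximum = TRUE)$maximum |> exp()
    l <- stats::optimize(function(v) ll_of(g, exp(v), p1),
                         c(log(lo), log(hi)), maximum = TRUE)$maximum |> exp()
    if (estimate_prior) {
      p1 <- stats::optimize(function(v) ll_of(g, l, v),
                            c(1e-4, 1 - 1e-4), maximum = TRUE)$maximum
    }
    cur <- ll_of(g, l, p1)
    if (cur - last < 1e-8) break
    last <- cur
  }
  if (l <= lo * 1.01 || all(X)) {
    warn("loss rate at lower boundary (all-present data?)")
  }
  structure(list(gain = g, loss = l, root_prior = p1, loglik = ll_of(g, l, p1),
                 rounds_used = used, posterior_threshold = posterior_threshold),
            class = "gainloss_model")
}

#' @export
print.gainloss_model <- function(x, ...) {
  cat(sprintf(
    "<gainloss_model> gain = %.4g, loss = %.4g, root prior = %.3f, logLik = %.2f\n",
    x$gain, x$loss, x$root_prior, x$loglik))
  invisible(x)
}

#' Per-branch gain/loss posterior probabilities
#'
#' Up-down (inside-outside) computation of the joint posterior
#' P(parent = absent, child = present | data) as the gain posterior and
#' P(parent = present, child = absent | data) as the loss posterior, for
#' every family and branch.
#'
#' @param pan A `pan_matrix`.
#' @param tree Rooted `phylo`.
#' @param model A `gainloss_model` (fitted or user-supplied).
#' @return A `branch_posteriors` list: `gain` and `loss` (branch x family
#'   matrices), `branches` tibble, `model`.
#' @export
branch_posteriors <- function(pan, tree, model) {
  X <- presence_view(pan)
  st <- tree_struct(tree, colnames(pan))
  ins <- inside_pass(st, X, model$gain, model$loss, model$root_prior)
  nn <- st$ntip + st$tree$Nnode
  Fn <- nrow(X)
  outside <- vector("list", nn)
  outside[[st$root]] <- matrix(ins$prior, 2, Fn)
  edges_parent_first <- rev(seq_len(nrow(st$edge)))  # postorder reversed
  child_edges <- split(seq_len(nrow(st$edge)), st$edge[, 1])
  gain_post <- loss_post <- matrix(0, nrow(st$edge), Fn)
  for (e in edges_parent_first) {
    par <- st$edge[e, 1]; chl <- st$edge[e, 2]
    sibs <- setdiff(child_edges[[as.character(par)]], e)
    S <- outside[[par]]
    for (se in sibs) {
      S <- S * (ins$P[[se]] %*% ins$L[[st$edge[se, 2]]])
    }
    P <- ins$P[[e]]
    # joint[a,b] per family = S[a,] * P[a,b] * inside_child[b,]
    Lc <- ins$L[[chl]]
    j11 <- S[1, ] * P[1, 1] * Lc[1, ]
    j12 <- S[1, ] * P[1, 2] * Lc[2, ]
    j21 <- S[2, ] * P[2, 1] * Lc[1, ]
    j22 <- S[2, ] * P[2, 2] * Lc[2, ]
    tot <- j11 + j12 + j21 + j22
    gain_post[e, ] <- j12 / tot
    loss_post[e, ] <- j21 / tot
    # outside message to child: sum over parent state
    outside[[chl]] <- rbind(S[1, ] * P[1, 1] + S[2, ] * P[2, 1],
                            S[1, ] * P[1, 2] + S[2, ] * P[2, 2])
  }
  branches <- tibble(
    branch = st$labels[st$edge[, 2]],
    parent = st$labels[st$edge[, 1]],
    length = st$len,
    is_terminal = st$edge[, 2] <= st$ntip
  )
  colnames(gain_post) <- colnames(loss_post) <- rownames(pan)
  rownames(gain_post) <- rownames(loss_post) <- branches$branch
  structure(list(gain = gain_post, loss = loss_post, branches = branches,
                 model = model),
            class = "branch_posteriors")
}

#' Threshold posteriors into likely events
#'
#' Counts, per branch, the families whose gain (resp. loss) posterior
#' exceeds the threshold ("likely events"), alongside the expected event
#' counts (summed posteriors). When `categories` is supplied, totals are
#' also attributed per pan-genome category.
#'
#' @param post A [branch_posteriors()] result.
#' @param threshold Posterior probability threshold (default 0.5).
#' @param categories Optional `pan_categories` for per-category attribution.
#' @return An `event_profile` tibble per branch with attributes `totals`
#'   (likely gains/losses and gain:loss ratio) and `per_category`.
#' @export
likely_events <- function(post, threshold = post$model$posterior_threshold,
                          categories = NULL) {
  stopifnot(inherits(post, "branch_posteriors"))
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  out <- post$branches |>
    mutate(
      expected_gains = unname(rowSums(post$gain)),
      expected_losses = unname(rowSums(post$loss)),
      likely_gains = unname(rowSums(post$gain > threshold)),
      likely_losses = unname(rowSums(post$loss > threshold))
    )
  totals <- list(gains = sum(out$likely_gains),
                 losses = sum(out$likely_losses))
  totals$gain_loss_ratio <- if (totals$losses > 0)
    totals$gains / totals$losses else Inf
  per_cat <- NULL
  if (!is.null(categories)) {
    cat_of <- stats::setNames(as.character(categories$category),
                              categories$family)[colnames(post$gain)]
    per_cat <- bind_rows(lapply(split(seq_along(cat_of), cat_of), function(ix) {
      tibble(gains = sum(post$gain[, ix, drop = FALSE] > threshold),
             losses = sum(post$loss[, ix, drop = FALSE] > threshold))
    }), .id = "category")
  }
  structure(out, class = c("event_profile", class(out)),
            totals = totals, per_category = per_cat, threshold = threshold)
}

#' Wagner parsimony reconstruction of gene-content events
#'
#' Sankoff dynamic programming with asymmetric costs (gain costs
#' `gain_penalty`, loss costs 1). Ties prefer the parent's state, then
#' absence (so an all-absent family stays absent at the root). Serves as an
#' independent oracle for the probabilistic model.
#'
#' @param pan A `pan_matrix`.
#' @param tree Rooted `phylo`.
#' @param gain_penalty Cost of a gain relative to a loss (default 2).
#' @return Tibble per branch: branch, parent, length, gains, losses; the
#'   minimal total cost in attribute `total_cost` and the per-family event
#'   calls in logical branch-by-family attributes `gain_events` /
#'   `loss_events`.
#' @export
wagner_parsimony <- function(pan, tree, gain_penalty = 2) {
  X <- presence_view(pan)
  st <- tree_struct(tree, colnames(pan))
  Fn <- nrow(X)
  nn <- st$ntip + st$tree$Nnode
  BIG <- 1e12
  trans <- matrix(c(0, 1, gain_penalty, 0), 2, 2)  # trans[from, to]
  cost <- vector("list", nn)
  for (tip in seq_len(st$ntip)) {
    x <- X[, st$tree$tip.label[tip]]
    cost[[tip]] <- rbind(ifelse(x, BIG, 0), ifelse(x, 0, BIG))
  }
  for (node in (st$ntip + 1L):nn) cost[[node]] <- matrix(0, 2, Fn)
  for (e in seq_len(nrow(st$edge))) {
    par <- st$edge[e, 1]; chl <- st$edge[e, 2]
    cc <- cost[[chl]]
    from1 <- pmin(cc[1, ] + trans[1, 1], cc[2, ] + trans[1, 2])
    from2 <- pmin(cc[1, ] + trans[2, 1], cc[2, ] + trans[2, 2])
    cost[[par]] <- cost[[par]] + rbind(from1, from2)
  }
  state <- matrix(NA_integer_, nn, Fn)
  rc <- cost[[st$root]]
  state[st$root, ] <- ifelse(rc[2, ] < rc[1, ], 2L, 1L)  # tie -> absent
  gains <- losses <- rep(0L, nrow(st$edge))
  for (e in rev(seq_len(nrow(st$edge)))) {
    par <- st$edge[e, 1]; chl <- st$edge[e, 2]
    a <- state[par, ]
    cc <- cost[[chl]]
    opt1 <- cc[1, ] + trans[cbind(a, 1L)]
    opt2 <- cc[2, ] + trans[cbind(a, 2L)]
    b <- ifelse(opt2 < opt1, 2L,
                ifelse(opt1 < opt2, 1L,
                       ifelse(a == 2L, 2L, 1L)))  # tie: parent state, then absent
    state[chl, ] <- b
    gains[e] <- sum(a == 1L & b == 2L)
    losses[e] <- sum(a == 2L & b == 1L)
  }
  total_cost <- sum(pmin(rc[1, ], rc[2, ]))
  gain_events <- loss_events <- matrix(
    FALSE, nrow(st$edge), Fn,
    dimnames = list(st$labels[st$edge[, 2]], rownames(X)))
  for (e in seq_len(nrow(st$edge))) {
    a <- state[st$edge[e, 1], ]; b <- state[st$edge[e, 2], ]
    gain_events[e, ] <- a == 1L & b == 2L
    loss_events[e, ] <- a == 2L & b == 1L
  }
  out <- tibble(branch = st$labels[st$edge[, 2]],
                parent = st$labels[st$edge[, 1]],
                length = st$len, gains = gains, losses = losses)
  structure(out, class = c("parsimony_events", class(out)),
            total_cost = total_cost,
            gain_events = gain_events, loss_events = loss_events)
}

#' Simulate presence/absence profiles under the two-state model
#'
#' Matched-model simulator for validating [fit_gainloss()]: each family's
#' root state is drawn from the root prior and evolves along the tree under
#' the gain/loss Markov process.
#'
#' @param tree Rooted `phylo`.
#' @param gain,loss Rates per unit branch length.
#' @param n_families Number of families.
#' @param root_prior Root presence probability (default: stationary
#'   gain/(gain+loss)).
#' @param seed Optional seed.
#' @return A `pan_matrix` (all families kept, including all-absent ones)
#'   with per-branch endpoint-change counts in attribute `events`.
#' @export
simulate_profiles <- function(tree, gain, loss, n_families,
                              root_prior = gain / (gain + loss),
                              seed = NULL) {
  st <- tree_struct(tree, tree$tip.label)
  with_seed(seed, {
    nn <- st$ntip + st$tree$Nnode
    state <- matrix(NA_integer_, nn, n_families)
    state[st$root, ] <- stats::rbinom(n_families, 1, root_prior)
    eo <- edges_preorder(st$tree)
    gains <- losses <- rep(0L, nrow(eo$edge))
    for (e in seq_len(nrow(eo$edge))) {
      par <- eo$edge[e, 1]; chl <- eo$edge[e, 2]
      P <- trans_mat(gain, loss, eo$length[e])
      a <- state[par, ]
      p_present <- ifelse(a == 1L, P[2, 2], P[1, 2])
      b <- as.integer(stats::runif(n_families) < p_present)
      state[chl, ] <- b
      gains[e] <- sum(a == 0L & b == 1L)
      losses[e] <- sum(a == 1L & b == 0L)
    }
    m <- t(state[seq_len(st$ntip), , drop = FALSE])
    rownames(m) <- sprintf("F%05d", seq_len(n_families))
    colnames(m) <- st$tree$tip.label
    structure(new_pan_matrix(m),
              events = tibble(branch = st$labels[eo$edge[, 2]],
                              gains = gains, losses = losses))
  })
}
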