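# Independent brute-force oracles shared by unit and acceptance tests.

# joint probability of presence/absence leaf data under the two-state
# gain/loss Markov model, by exhaustive enumeration of internal states
enum_loglik <- function(tree, X, gain, loss, prior1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  trans <- function(a, b, t) {
    s <- gain + loss
    if (s == 0 || t <= 0) return(as.numeric(a == b))
    e <- exp(-s * t)
    if (a == 0 && b == 0) (loss + gain * e) / s
    else if (a == 0 && b == 1) gain * (1 - e) / s
    else if (a == 1 && b == 0) loss * (1 - e) / s
    else (gain + loss * e) / s
  }
  total <- 0
  for (f in seq_len(nrow(X))) {
    obs <- X[f, tr$tip.label]
    lik <- 0
    for (code in 0:(2^tr$Nnode - 1)) {
      states <- c(obs, as.integer(intToBits(code))[1:tr$Nnode])
      p <- if (states[ntip + 1] == 1) prior1 else 1 - prior1
      for (e in seq_len(nrow(tr$edge))) {
        p <- p * trans(states[tr$edge[e, 1]], states[tr$edge[e, 2]],
                       tr$edge.length[e])
      }
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# minimal Wagner cost of one family by exhaustive ancestral-state search
wagner_cost_oracle <- function(tree, obs, gain_penalty = 2) {
  tr <- ape::reorder.phylo(tree, "postorder")
  obs <- obs[tr$tip.label]
  best <- Inf
  for (code in 0:(2^tr$Nnode - 1)) {
    states <- c(obs, as.integer(intToBits(code))[1:tr$Nnode])
    cost <- 0
    for (e in seq_len(nrow(tr$edge))) {
      a <- states[tr$edge[e, 1]]; b <- states[tr$edge[e, 2]]
      cost <- cost + if (a == 0 && b == 1) gain_penalty else
        if (a == 1 && b == 0) 1 else 0
    }
    best <- min(best, cost)
  }
  best
}

# tetranucleotide z-scores by naive word counting over both strands
tetra_z_oracle <- function(s) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  count_words <- function(x, k) {
    words <- substring(x, 1:(nchar(x) - k + 1), k:nchar(x))
    lv <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1], 1,
                paste0, collapse = "")
    table(factor(words, levels = sort(lv)))
  }
  n4 <- count_words(s, 4) + count_words(rc, 4)
  n3 <- count_words(s, 3) + count_words(rc, 3)
  n2 <- count_words(s, 2) + count_words(rc, 2)
  w <- names(n4)
  e <- ifelse(n2[substr(w, 2, 3)] > 0,
              as.numeric(n3[substr(w, 1, 3)]) * as.numeric(n3[substr(w, 2, 4)]) /
                as.numeric(n2[substr(w, 2, 3)]), 0)
  setNames(as.numeric(ifelse(e > 0, (as.numeric(n4) - e) / sqrt(e), 0)), w)
}
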