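# Independent oracles used by the unit and acceptance suites.  These are
# deliberately written from first principles (choose()/subset enumeration/
# all-pairs counting), not by calling the implementation paths they check.

# two-sided Fisher p for a 2x2 allele table by direct enumeration of all
# tables with the observed margins, probabilities from binomial coefficients
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b            # case alleles
  m2 <- c + d            # control alleles
  k <- a + c             # total alt alleles
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  pr <- exp(logp)
  obs <- pr[match(a, xs)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# one-sided (greater) hypergeometric tail: P(overlap >= k)
oracle_hyper_greater <- function(k, n_white, n_black, n_draw) {
  xs <- k:min(n_white, n_draw)
  xs <- xs[xs >= max(0, n_draw - n_black)]
  sum(exp(lchoose(n_white, xs) + lchoose(n_black, n_draw - xs) -
            lchoose(n_white + n_black, n_draw)))
}

# MCODE vertex weight by exhaustive subset enumeration over the closed
# neighborhood: kmax = max over subsets of the minimum internal degree;
# the kmax-core is the union of all subsets attaining it
oracle_mcode_weight <- function(adj, v) {
  nb <- c(v, which(adj[v, ] > 0))
  n <- length(nb)
  if (n < 2) return(0)
  best_k <- 0
  core <- integer()
  subsets <- seq_len(2^n - 1)
  for (s in subsets) {
    memb <- nb[bitwAnd(s, 2^(seq_len(n) - 1)) > 0]
    if (length(memb) < 2) next
    degs <- rowSums(adj[memb, memb, drop = FALSE])
    mk <- min(degs)
    if (mk > best_k) {
      best_k <- mk; core <- memb
    } else if (mk == best_k && best_k > 0) {
      core <- union(core, memb)
    }
  }
  if (best_k == 0) return(0)
  m <- length(core)
  e <- sum(adj[core, core]) / 2
  best_k * (2 * e / (m * (m - 1)))
}

# AUC by all-pairs comparison with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random simple graph as a 0/1 adjacency matrix
random_adjacency <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  dimnames(adj) <- list(letters[seq_len(n)], letters[seq_len(n)])
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
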