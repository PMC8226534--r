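# Independent oracle implementations used only by the tests. These stay
# deliberately naive (explicit path traversal, pairwise peeling, numerical
# integration) so they share no code path with the package.

# shared-path-length matrix by explicit root-to-tip path traversal
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  root <- n + 1L
  path_edges <- lapply(seq_len(n), function(i) {
    v <- i; out <- integer(0)
    while (v != root) { out <- c(out, v); v <- parent[v] }
    out   # child nodes of the edges on the path
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(path_edges[[i]], path_edges[[j]])
      C[i, j] <- sum(elen[shared])
    }
  }
  C
}

# Brownian-motion log-likelihood by pairwise peeling (Felsenstein pruning),
# arbitrary node degrees, fixed mean theta0 and rate sigma2
oracle_bm_loglik <- function(tree, x, sigma2, theta0) {
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  mu <- numeric(nn); v <- numeric(nn)
  mu[seq_len(n)] <- x[tree$tip.label]
  lnl <- 0
  children <- split(tree$edge[, 2], tree$edge[, 1])
  elen <- numeric(nn); elen[tree$edge[, 2]] <- tree$edge.length
  po_nodes <- unique(tree$edge[ape::postorder(tree), 1])
  for (node in po_nodes) {
    kids <- children[[as.character(node)]]
    est <- cbind(mu[kids], v[kids] + elen[kids])
    while (nrow(est) > 1) {
      V1 <- est[1, 2]; V2 <- est[2, 2]
      lnl <- lnl + stats::dnorm(est[1, 1] - est[2, 1], 0,
                                sqrt(sigma2 * (V1 + V2)), log = TRUE)
      comb <- c((est[1, 1] * V2 + est[2, 1] * V1) / (V1 + V2),
                V1 * V2 / (V1 + V2))
      est <- rbind(comb, est[-(1:2), , drop = FALSE])
    }
    mu[node] <- est[1, 1]; v[node] <- est[1, 2]
  }
  root <- n + 1L
  lnl + stats::dnorm(mu[root], theta0, sqrt(sigma2 * v[root]), log = TRUE)
}

# OU log-likelihood via the node-height transform: on an ultrametric tree the
# stationary OU covariance is a monotone function of the BM covariance, so a
# branch-length rescaling turns the OU model into BM with rate 1 (tree
# traversal route, independent of the dense-matrix path). `mu` is the OU mean
# vector (theta weights applied by the caller).
oracle_ou_loglik <- function(tree, x, mu, sigma2, alpha) {
  g <- function(h, T) sigma2 / (2 * alpha) * exp(-2 * alpha * T) *
    (exp(2 * alpha * h) - 1)
  n <- length(tree$tip.label)
  depths <- numeric(max(tree$edge))
  for (e in rev(ape::postorder(tree))) {
    depths[tree$edge[e, 2]] <- depths[tree$edge[e, 1]] + tree$edge.length[e]
  }
  T <- max(depths[seq_len(n)])
  tr2 <- tree
  tr2$edge.length <- g(depths[tree$edge[, 2]], T) - g(depths[tree$edge[, 1]], T)
  r <- stats::setNames(x[tree$tip.label] - mu[tree$tip.label], tree$tip.label)
  oracle_bm_loglik(tr2, r, 1, 0)
}

# expected total number of state transitions on a branch of length t
# conditional on endpoint states (a, b), by numerical integration
oracle_expected_jumps <- function(Q, t, a, b) {
  P <- function(s) {
    ed <- eigen(Q, symmetric = TRUE)
    ed$vectors %*% (exp(ed$values * s) * t(ed$vectors))
  }
  k <- ncol(Q)
  Pab <- P(t)[a, b]
  total <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j || Q[i, j] == 0) next
    f <- Vectorize(function(s) P(s)[a, i] * P(t - s)[j, b])
    total <- total + Q[i, j] * stats::integrate(f, 0, t, rel.tol = 1e-9)$value
  }
  total / Pab
}

# exact posterior over internal-node state combinations of a small tree
# (uniform root prior), by complete enumeration
oracle_node_state_posterior <- function(tree, tip_states_idx, Q) {
  k <- ncol(Q)
  n <- length(tree$tip.label)
  internal <- (n + 1L):max(tree$edge)
  P <- function(s) {
    ed <- eigen(Q, symmetric = TRUE)
    ed$vectors %*% (exp(ed$values * s) * t(ed$vectors))
  }
  Pmats <- lapply(tree$edge.length, P)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  like <- apply(combos, 1, function(cc) {
    st <- integer(max(tree$edge))
    st[seq_len(n)] <- tip_states_idx
    st[internal] <- cc
    prod(vapply(seq_len(nrow(tree$edge)), function(e)
      Pmats[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]], numeric(1))) / k
  })
  list(combos = combos, prob = like / sum(like), internal = internal)
}
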