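#' @title Evolutionary models of nectar traits over pollinator regimes
#' @description
#' Maximum-likelihood fitting and AICc comparison of five Gaussian models of
#' continuous trait evolution: BM1 (one Brownian rate), BMS (per-regime
#' Brownian rates), OU1 (single-optimum Ornstein-Uhlenbeck), and OU-PG
#' (multi-optimum OU with one optimum per pollinator regime, shared rate and
#' selection strength). Regimes are painted on the tree either from a known
#' history or by stochastic character mapping under a fitted Mk model.
#' @name evo_models
NULL

## ---- regime paintings -------------------------------------------------

#' Construct a regime painting
#'
#' A painting assigns a selective regime to every point of every branch.
#' `segments[[e]]` is a data.frame with columns `length` and `regime`
#' describing edge `e` (row of `tree$edge`) from its rootward end to its
#' tipward end; segment lengths must sum to the branch length.
#'
#' @param tree A `phylo` object.
#' @param segments List of per-edge segment data.frames.
#' @param tip_states Named regime labels for the tips.
#' @param root_state Regime at the root.
#' @return An object of class `regime_painting`.
#' @export
regime_painting <- function(tree, segments, tip_states, root_state) {
  p <- list(tree = tree, segments = segments,
            tip_states = tip_states[tree$tip.label], root_state = root_state,
            regimes = sort(unique(c(root_state, tip_states,
                                    unlist(lapply(segments, `[[`, "regime"))))))
  class(p) <- "regime_painting"
  validate_painting(p)
  p
}

#' @export
print.regime_painting <- function(x, ...) {
  cat(sprintf("regime painting: %d tips, regimes {%s}, root state %s\n",
              length(x$tree$tip.label), paste(x$regimes, collapse = ", "),
              x$root_state))
  invisible(x)
}

validate_painting <- function(p) {
  tr <- p$tree
  stopifnot(length(p$segments) == nrow(tr$edge))
  for (e in seq_len(nrow(tr$edge))) {
    seg <- p$segments[[e]]
    if (abs(sum(seg$length) - tr$edge.length[e]) > 1e-8 * max(1, tr$edge.length[e]))
      stop("segment lengths do not sum to branch length on edge ", e, call. = FALSE)
    child <- tr$edge[e, 2]
    if (child <= length(tr$tip.label)) {
      tip <- tr$tip.label[child]
      if (seg$regime[nrow(seg)] != p$tip_states[[tip]])
        stop("tip-adjacent segment regime differs from tip state at ", tip,
             call. = FALSE)
    }
  }
  invisible(p)
}

#' Single-regime painting
#'
#' @param tree A `phylo` object.
#' @param regime Regime label painted everywhere.
#' @return A `regime_painting`.
#' @export
uniform_painting <- function(tree, regime = "all") {
  tree <- read_phylogeny(tree)
  segs <- lapply(tree$edge.length, function(l)
    data.frame(length = l, regime = regime, stringsAsFactors = FALSE))
  regime_painting(tree, segs,
                  stats::setNames(rep(regime, length(tree$tip.label)),
                                  tree$tip.label), regime)
}

#' Collapse painting regimes into super-regimes
#'
#' Relabels regimes by a grouping map, e.g. all insect pollinator groups into
#' one `"insects"` regime for the two-optimum OU model.
#'
#' @param painting A `regime_painting`.
#' @param map Named character vector, `regime = "super_regime"`.
#' @return A `regime_painting` with relabelled regimes.
#' @export
collapse_regimes <- function(painting, map) {
  relabel <- function(r) {
    out <- r
    hit <- r %in% names(map)
    out[hit] <- unname(map[r[hit]])
    out
  }
  segs <- lapply(painting$segments, function(seg) {
    seg$regime <- relabel(seg$regime)
    # merge now-adjacent identical regimes
    keep <- c(TRUE, seg$regime[-1] != seg$regime[-nrow(seg)])
    grp <- cumsum(keep)
    data.frame(length = as.numeric(tapply(seg$length, grp, sum)),
               regime = seg$regime[keep], stringsAsFactors = FALSE)
  })
  regime_painting(painting$tree, segs, relabel(painting$tip_states),
                  relabel(painting$root_state))
}

# parent pointer vector; root maps to 0
parent_vector <- function(tree) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

# depth (distance from root) of every node
node_depths <- function(tree) {
  d <- numeric(max(tree$edge))
  for (e in rev(ape::postorder(tree))) {  # preorder: parent before child
    d[tree$edge[e, 2]] <- d[tree$edge[e, 1]] + tree$edge.length[e]
  }
  d
}

is_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) <= tol * max(d)
}

# time spent in each regime on the root-to-node path, for every node
regime_occupancy <- function(painting) {
  tr <- painting$tree
  regimes <- painting$regimes
  nn <- max(tr$edge)
  occ <- matrix(0, nn, length(regimes), dimnames = list(NULL, regimes))
  edge_occ <- matrix(vapply(painting$segments, function(seg) {
    v <- stats::setNames(numeric(length(regimes)), regimes)
    s <- tapply(seg$length, seg$regime, sum)
    v[names(s)] <- s
    v
  }, numeric(length(regimes))), ncol = length(regimes), byrow = TRUE,
  dimnames = list(NULL, regimes))
  po <- rev(ape::postorder(tr))     # preorder: parent before child
  for (e in po) {
    occ[tr$edge[e, 2], ] <- occ[tr$edge[e, 1], ] + edge_occ[e, ]
  }
  occ
}

# root-path segments with absolute times (from the root) for every tip:
# data.frame(tip, t_start, t_end, regime), plus per-tip depths
painting_tip_paths <- function(painting) {
  tr <- painting$tree
  n <- length(tr$tip.label)
  parent <- parent_vector(tr)
  root <- n + 1L
  edge_of_child <- integer(max(tr$edge))
  edge_of_child[tr$edge[, 2]] <- seq_len(nrow(tr$edge))
  depths <- node_depths(tr)
  # absolute-time segment table per edge, computed once
  edge_tab <- lapply(seq_len(nrow(tr$edge)), function(e) {
    seg <- painting$segments[[e]]
    t0 <- depths[tr$edge[e, 1]]
    ends <- t0 + cumsum(seg$length)
    list(t_start = c(t0, ends[-length(ends)]), t_end = ends,
         regime = seg$regime)
  })
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    edges <- integer(0); v <- i
    while (v != root) { edges <- c(edge_of_child[v], edges); v <- parent[v] }
    tabs <- edge_tab[edges]
    rows[[i]] <- data.frame(
      tip = i,
      t_start = unlist(lapply(tabs, `[[`, "t_start")),
      t_end = unlist(lapply(tabs, `[[`, "t_end")),
      regime = unlist(lapply(tabs, `[[`, "regime")),
      stringsAsFactors = FALSE)
  }
  list(paths = do.call(rbind, rows),
       tip_depth = depths[seq_len(n)])
}

## ---- Mk model ---------------------------------------------------------

mk_Q <- function(rates, states, model) {
  k <- length(states)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (model == "ER") {
    Q[] <- rates[1]
  } else {
    Q[lower.tri(Q)] <- rates
    Q <- Q + t(Q)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

# transition probability matrices for a symmetric Q via one eigendecomposition
mk_P_factory <- function(Q) {
  ed <- eigen(Q, symmetric = TRUE)
  function(t) {
    P <- ed$vectors %*% (exp(ed$values * t) * t(ed$vectors))
    P[P < 0] <- 0
    P
  }
}

# pruning-algorithm log-likelihood of tip states under Q (uniform root prior)
mk_loglik <- function(tree, states_idx, Q) {
  k <- ncol(Q)
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  P_of <- mk_P_factory(Q)
  L <- matrix(1, nn, k)
  L[seq_len(n), ] <- 0
  L[cbind(seq_len(n), states_idx)] <- 1
  logscale <- 0
  po <- ape::postorder(tree)
  for (e in po) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    contrib <- as.numeric(P_of(tree$edge.length[e]) %*% L[ch, ])
    L[par, ] <- L[par, ] * contrib
    m <- max(L[par, ])
    if (m > 0 && m < 1e-10) { L[par, ] <- L[par, ] / m; logscale <- logscale + log(m) }
  }
  root <- n + 1L
  log(sum(L[root, ] / k)) + logscale
}

#' Fit an Mk model of discrete regime evolution
#'
#' Equal-rates (default) or symmetric-rates continuous-time Markov model,
#' fitted by maximum likelihood with the pruning algorithm and a uniform
#' root prior. If only one state is observed the rate sits at the zero
#' boundary and the fit is flagged.
#'
#' @param tree A binary `phylo` object.
#' @param tip_states Named character vector of observed states.
#' @param model `"ER"` or `"SYM"`.
#' @return List of class `mk_fit`: `Q`, `rates`, `states`, `loglik`, `model`,
#'   `boundary` (single observed state), `tip_states`.
#' @export
fit_mk <- function(tree, tip_states, model = c("ER", "SYM")) {
  model <- match.arg(model)
  tree <- read_phylogeny(tree)
  tip_states <- tip_states[tree$tip.label]
  if (anyNA(tip_states)) stop("tip state missing for some tips", call. = FALSE)
  states <- sort(unique(tip_states))
  if (length(states) < 2) {
    Q <- matrix(0, 1, 1, dimnames = list(states, states))
    out <- list(Q = Q, rates = 0, states = states, loglik = 0, model = model,
                boundary = TRUE, tip_states = tip_states, tree = tree)
    class(out) <- "mk_fit"
    return(out)
  }
  k <- length(states)
  idx <- match(tip_states, states)
  n_rates <- if (model == "ER") 1L else k * (k - 1L) / 2L
  total_len <- sum(tree$edge.length)
  nll <- function(logr) -mk_loglik(tree, idx, mk_Q(exp(logr), states, model))
  start <- log(rep(max(k, 2) / total_len, n_rates))
  if (n_rates == 1) {
    opt <- stats::optimize(function(lr) nll(lr), c(log(1e-8 / total_len), log(1e4 / total_len)))
    rates <- exp(opt$minimum); lnl <- -opt$objective
  } else {
    opt <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = log(1e-8 / total_len), upper = log(1e4 / total_len))
    rates <- exp(opt$par); lnl <- -opt$value
  }
  out <- list(Q = mk_Q(rates, states, model), rates = rates, states = states,
              loglik = lnl, model = model, boundary = FALSE,
              tip_states = tip_states, tree = tree)
  class(out) <- "mk_fit"
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat(sprintf("Mk (%s) fit: %d states, lnL = %.4f%s\n", x$model,
              length(x$states), x$loglik,
              if (x$boundary) " [rate at zero boundary]" else ""))
  invisible(x)
}

# forward CTMC path from state `a` over time `t`; returns segment table
forward_ctmc <- function(a, t, Q, states) {
  s <- a; time <- 0
  seg_len <- numeric(0); seg_state <- character(0)
  repeat {
    rate <- -Q[s, s]
    wait <- if (rate > 0) stats::rexp(1, rate) else Inf
    if (time + wait >= t) {
      seg_len <- c(seg_len, t - time); seg_state <- c(seg_state, states[s])
      break
    }
    seg_len <- c(seg_len, wait); seg_state <- c(seg_state, states[s])
    time <- time + wait
    s <- sample.int(length(states), 1, prob = pmax(Q[s, ], 0))
  }
  list(segments = data.frame(length = seg_len, regime = seg_state,
                             stringsAsFactors = FALSE),
       end = s)
}

# merge adjacent equal-regime segments
merge_segments <- function(seg) {
  keep <- c(TRUE, seg$regime[-1] != seg$regime[-nrow(seg)])
  grp <- cumsum(keep)
  data.frame(length = as.numeric(tapply(seg$length, grp, sum)),
             regime = seg$regime[keep], stringsAsFactors = FALSE)
}

# endpoint-conditioned CTMC path by uniformization (exact)
uniformized_bridge <- function(a, b, t, Q, states) {
  k <- length(states)
  mu <- max(-diag(Q))
  if (mu == 0) {
    return(data.frame(length = t, regime = states[a], stringsAsFactors = FALSE))
  }
  R <- diag(k) + Q / mu
  nmax <- max(10, stats::qpois(1 - 1e-12, mu * t) + 10)
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(k)
  for (m in seq_len(nmax)) Rpow[[m + 1]] <- Rpow[[m]] %*% R
  wn <- vapply(0:nmax, function(n) stats::dpois(n, mu * t) * Rpow[[n + 1]][a, b],
               numeric(1))
  n_jumps <- sample.int(nmax + 1, 1, prob = wn) - 1L
  if (n_jumps == 0) {
    return(data.frame(length = t, regime = states[a], stringsAsFactors = FALSE))
  }
  seq_states <- integer(n_jumps + 1)
  seq_states[1] <- a; seq_states[n_jumps + 1] <- b
  if (n_jumps > 1) {
    for (m in 2:n_jumps) {
      prev <- seq_states[m - 1]
      w <- R[prev, ] * Rpow[[n_jumps - m + 2]][, b]
      seq_states[m] <- sample.int(k, 1, prob = pmax(w, 0))
    }
  }
  times <- sort(stats::runif(n_jumps, 0, t))
  bounds <- c(0, times, t)
  seg <- data.frame(length = diff(bounds), regime = states[seq_states],
                    stringsAsFactors = FALSE)
  merge_segments(seg[seg$length > 0 | seq_along(seg$length) == nrow(seg), ,
                     drop = FALSE])
}

#' Stochastic character maps of regimes
#'
#' Samples regime histories conditional on the tip states and a fitted Mk
#' model: node states are drawn root-down from the conditional likelihoods,
#' then each branch history is sampled conditional on its endpoint states
#' (rejection sampling with a retry cap, falling back to exact
#' uniformization sampling).
#'
#' @param tree A `phylo` object (taken from `fit` if missing).
#' @param tip_states Named states (taken from `fit` if missing).
#' @param fit An `mk_fit` from [fit_mk()].
#' @param n_maps Number of maps (default 10).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling cap per branch before uniformization.
#' @return List of `regime_painting` objects.
#' @export
stochastic_map <- function(tree = fit$tree, tip_states = fit$tip_states, fit,
                           n_maps = 10, seed = 1L, max_tries = 200) {
  tree <- read_phylogeny(tree)
  tip_states <- tip_states[tree$tip.label]
  states <- fit$states
  k <- length(states)
  if (k == 1) {
    return(replicate(n_maps, uniform_painting(tree, states), simplify = FALSE))
  }
  Q <- fit$Q
  P_of <- mk_P_factory(Q)
  n <- length(tree$tip.label)
  nn <- max(tree$edge)
  idx <- match(tip_states, states)
  # conditional (partial) likelihoods of each node's subtree
  L <- matrix(1, nn, k)
  L[seq_len(n), ] <- 0
  L[cbind(seq_len(n), idx)] <- 1
  po <- ape::postorder(tree)
  Pmats <- lapply(tree$edge.length, P_of)
  for (e in po) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    L[par, ] <- L[par, ] * as.numeric(Pmats[[e]] %*% L[ch, ])
    L[par, ] <- L[par, ] / max(L[par, ])
  }
  root <- n + 1L
  pre <- rev(po)
  with_seed(seed, replicate(n_maps, {
    node_state <- integer(nn)
    node_state[root] <- sample.int(k, 1, prob = L[root, ])
    segs <- vector("list", nrow(tree$edge))
    for (e in pre) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      a <- node_state[par]
      w <- Pmats[[e]][a, ] * L[ch, ]
      b <- sample.int(k, 1, prob = pmax(w, 0))
      node_state[ch] <- b
      t_e <- tree$edge.length[e]
      path <- NULL
      for (try in seq_len(max_tries)) {
        cand <- forward_ctmc(a, t_e, Q, states)
        if (cand$end == b) { path <- merge_segments(cand$segments); break }
      }
      if (is.null(path)) path <- uniformized_bridge(a, b, t_e, Q, states)
      segs[[e]] <- path
    }
    regime_painting(tree, segs,
                    stats::setNames(states[node_state[seq_len(n)]], tree$tip.label),
                    states[node_state[root]])
  }, simplify = FALSE))
}

## ---- Gaussian trait models --------------------------------------------

#' Small-sample corrected AIC
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param loglik Log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of tips.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# OU stationary covariance structure (ultrametric tree):
# V = sigma2/(2 alpha) * exp(-alpha D) * (1 - exp(-2 alpha C)); this returns
# V / sigma2 so sigma2 can be profiled out.
ou_structure <- function(C, D, alpha) {
  exp(-alpha * D) * (-expm1(-2 * alpha * C)) / (2 * alpha)
}

# OU optimum weight matrix (tips x regimes), stationary-root convention:
# the root's regime absorbs exp(-alpha * T_i) so each row sums to 1.
# `paths` caches painting_tip_paths() across alpha evaluations.
ou_weight_matrix <- function(painting, alpha, paths = painting_tip_paths(painting)) {
  tr <- painting$tree
  n <- length(tr$tip.label)
  regimes <- painting$regimes
  pp <- paths$paths
  T_i <- paths$tip_depth[pp$tip]
  w <- exp(-alpha * (T_i - pp$t_end)) - exp(-alpha * (T_i - pp$t_start))
  W <- matrix(0, n, length(regimes), dimnames = list(tr$tip.label, regimes))
  acc <- rowsum(w, group = paste(pp$tip, pp$regime, sep = "\r"))
  key <- strsplit(rownames(acc), "\r", fixed = TRUE)
  W[cbind(as.integer(vapply(key, `[`, "", 1)),
          match(vapply(key, `[`, "", 2), regimes))] <- acc[, 1]
  W[, painting$root_state] <- W[, painting$root_state] +
    exp(-alpha * paths$tip_depth)
  W
}

gaussian_loglik <- function(x, mu, V) {
  n <- length(x)
  ch <- tryCatch(chol(V), error = function(e)
    stop("model covariance not positive definite", call. = FALSE))
  r <- x - mu
  z <- forwardsolve(t(ch), r)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(z^2))
}

#' Log-likelihood of a trait-evolution model at given parameters
#'
#' Dense multivariate-normal likelihood of tip values under BM1, BMS, OU1,
#' or OU-PG; OU models require an ultrametric tree (the stationary OU
#' covariance used here assumes contemporaneous tips).
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector.
#' @param model `"BM1"`, `"BMS"`, `"OU1"`, or `"OUPG"`.
#' @param params List: `sigma2` (scalar, or named per regime for BMS),
#'   `theta0` (BM root/mean), `alpha` and `theta` (scalar for OU1, named per
#'   regime for OUPG) as required by the model.
#' @param painting A `regime_painting` (required for BMS and OUPG).
#' @return Log-likelihood.
#' @export
model_likelihood <- function(tree, x, model = c("BM1", "BMS", "OU1", "OUPG"),
                             params, painting = NULL) {
  model <- match.arg(model)
  tree <- read_phylogeny(tree)
  x <- check_trait(tree, x)
  C <- vcv_matrix(tree)
  if (model == "BM1") {
    return(gaussian_loglik(x, rep(params$theta0, length(x)), params$sigma2 * C))
  }
  if (model == "BMS") {
    stopifnot(!is.null(painting))
    occ <- regime_occupancy(painting)
    mrca <- ape::mrca(tree)
    V <- matrix(0, length(x), length(x))
    for (r in names(params$sigma2)) {
      V <- V + params$sigma2[[r]] * matrix(occ[mrca, r], length(x), length(x))
    }
    diag(V) <- vapply(seq_along(x), function(i)
      sum(unlist(params$sigma2[colnames(occ)]) * occ[i, ]), numeric(1))
    return(gaussian_loglik(x, rep(params$theta0, length(x)), V))
  }
  if (!is_ultrametric(tree)) {
    stop("OU models require an ultrametric tree", call. = FALSE)
  }
  D <- patristic_matrix(tree)
  S <- ou_structure(C, D, params$alpha)
  if (model == "OU1") {
    return(gaussian_loglik(x, rep(params$theta, length(x)), params$sigma2 * S))
  }
  stopifnot(!is.null(painting))
  W <- ou_weight_matrix(painting, params$alpha)
  theta <- unlist(params$theta)[colnames(W)]
  gaussian_loglik(x, as.numeric(W %*% theta), params$sigma2 * S)
}

# profile log-likelihood infrastructure: given a covariance *structure* S
# (V = sigma2 * S) and a design W for the mean (mu = W theta), the GLS
# theta-hat and sigma2-hat are closed-form.
profile_gaussian <- function(x, W, S) {
  n <- length(x)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Si_x <- backsolve(ch, forwardsolve(t(ch), x))
  Si_W <- backsolve(ch, forwardsolve(t(ch), W))
  A <- crossprod(W, Si_W)
  theta <- tryCatch(solve(A, crossprod(W, Si_x)), error = function(e) NULL)
  if (is.null(theta)) return(NULL)
  r <- x - as.numeric(W %*% theta)
  Si_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Si_r) / n
  if (s2 <= 0) return(NULL)
  lnl <- -0.5 * (n * log(2 * pi * s2) + 2 * sum(log(diag(ch))) + n)
  list(loglik = lnl, sigma2 = s2, theta = as.numeric(theta))
}

fit_bm1 <- function(x, C, n) {
  pr <- profile_gaussian(x, matrix(1, n, 1), C)
  list(model = "BM1", k = 2L, n = n,
       sigma2 = pr$sigma2, alpha = NA_real_,
       theta = c(theta0 = pr$theta), loglik = pr$loglik,
       aicc = aicc(pr$loglik, 2L, n))
}

fit_ou_profile <- function(x, C, D, painting, n, two_plus_R, alpha_grid_n = 24) {
  depth <- max(diag(C))
  lo <- 1e-9; hi <- 50 / depth
  W_of <- if (is.null(painting)) {
    function(alpha) matrix(1, n, 1)
  } else {
    paths <- painting_tip_paths(painting)
    function(alpha) ou_weight_matrix(painting, alpha, paths)
  }
  prof <- function(log_alpha) {
    alpha <- exp(log_alpha)
    pr <- profile_gaussian(x, W_of(alpha), ou_structure(C, D, alpha))
    if (is.null(pr)) -1e12 else pr$loglik   # finite penalty keeps optimize() quiet
  }
  grid <- seq(log(lo), log(hi), length.out = alpha_grid_n)
  vals <- vapply(grid, prof, numeric(1))
  best <- which.max(vals)
  lower <- grid[max(1, best - 1)]; upper <- grid[min(alpha_grid_n, best + 1)]
  opt <- stats::optimize(prof, c(lower, upper), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), cbind(grid, vals))
  top <- cand[which.max(cand[, 2]), ]
  alpha <- exp(top[1])
  pr <- profile_gaussian(x, W_of(alpha), ou_structure(C, D, alpha))
  theta <- pr$theta
  names(theta) <- if (is.null(painting)) "theta" else colnames(W_of(alpha))
  k <- if (is.null(painting)) 3L else two_plus_R
  list(model = if (is.null(painting)) "OU1" else "OUPG", k = k, n = n,
       sigma2 = pr$sigma2, alpha = alpha, theta = theta, loglik = pr$loglik,
       aicc = aicc(pr$loglik, k, n))
}

fit_bms <- function(x, C, painting, n) {
  occ <- regime_occupancy(painting)
  mrca <- ape::mrca(painting$tree)
  regimes <- painting$regimes
  R <- length(regimes)
  occ_mats <- lapply(regimes, function(r) {
    M <- matrix(occ[mrca, r], n, n)
    diag(M) <- occ[seq_len(n), r]
    M
  })
  ones <- matrix(1, n, 1)
  prof <- function(eta) {   # eta: log relative rates for regimes 2..R
    rel <- c(1, exp(eta))
    S <- Reduce(`+`, Map(`*`, rel, occ_mats))
    pr <- profile_gaussian(x, ones, S)
    if (is.null(pr)) 1e12 else -pr$loglik
  }
  if (R == 1) {
    opt_par <- numeric(0); val <- prof(numeric(0))
  } else {
    starts <- list(rep(0, R - 1), rep(1, R - 1), rep(-1, R - 1))
    fits <- lapply(starts, function(s)
      stats::optim(s, prof, method = if (R == 2) "Brent" else "Nelder-Mead",
                   lower = if (R == 2) -20 else -Inf,
                   upper = if (R == 2) 20 else Inf))
    bi <- which.min(vapply(fits, `[[`, numeric(1), "value"))
    opt_par <- fits[[bi]]$par; val <- fits[[bi]]$value
  }
  rel <- c(1, exp(opt_par))
  S <- Reduce(`+`, Map(`*`, rel, occ_mats))
  pr <- profile_gaussian(x, ones, S)
  k <- 1L + R
  list(model = "BMS", k = k, n = n,
       sigma2 = stats::setNames(pr$sigma2 * rel, regimes),
       alpha = NA_real_, theta = c(theta0 = pr$theta), loglik = pr$loglik,
       aicc = aicc(pr$loglik, k, n))
}

#' Fit a trait-evolution model by maximum likelihood
#'
#' BM1 and the profiled parameters of BMS/OU are obtained in closed form by
#' generalized least squares; the remaining dimensions (OU selection strength
#' `alpha`, BMS relative rates) are optimized by a bounded deterministic
#' multi-start search (log-spaced `alpha` grid on `[1e-9, 50/depth]` with
#' local refinement; three starts for BMS relative rates). For regime models,
#' supply one or more paintings; with several (stochastic maps), the model is
#' fitted per map and `loglik`/`aicc` are averaged, per-map fits retained.
#'
#' @param tree A `phylo` object (ultrametric for OU models).
#' @param x Named trait vector.
#' @param model `"BM1"`, `"BMS"`, `"OU1"`, or `"OUPG"`.
#' @param paintings A `regime_painting` or list of them (BMS/OUPG only).
#' @return List of class `model_fit`: `model`, `k`, `n`, `sigma2`, `alpha`,
#'   `theta`, `loglik`, `aicc`, and `per_map` (for multiple paintings).
#' @export
fit_model <- function(tree, x, model = c("BM1", "BMS", "OU1", "OUPG"),
                      paintings = NULL) {
  model <- match.arg(model)
  tree <- read_phylogeny(tree)
  x <- check_trait(tree, x)
  n <- length(x)
  C <- vcv_matrix(tree)
  if (model %in% c("OU1", "OUPG") && !is_ultrametric(tree)) {
    stop("OU models require an ultrametric tree", call. = FALSE)
  }
  D <- if (model %in% c("OU1", "OUPG")) patristic_matrix(tree) else NULL
  if (model %in% c("BMS", "OUPG")) {
    if (is.null(paintings)) stop("regime model needs painting(s)", call. = FALSE)
    if (inherits(paintings, "regime_painting")) paintings <- list(paintings)
    fits <- lapply(paintings, function(p) {
      if (model == "BMS") fit_bms(x, C, p, n)
      else fit_ou_profile(x, C, D, p, n,
                          two_plus_R = 2L + length(p$regimes))
    })
    out <- fits[[1]]
    out$loglik <- mean(vapply(fits, `[[`, numeric(1), "loglik"))
    out$aicc <- mean(vapply(fits, `[[`, numeric(1), "aicc"))
    if (length(fits) > 1) out$per_map <- fits
  } else if (model == "BM1") {
    out <- fit_bm1(x, C, n)
  } else {
    out <- fit_ou_profile(x, C, D, NULL, n, two_plus_R = 3L)
  }
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: lnL = %.4f, AICc = %.4f (k = %d, n = %d)\n",
              x$model, x$loglik, x$aicc, x$k, x$n))
  invisible(x)
}

#' AICc comparison table across models and traits
#'
#' @param fits Named list (traits) of named lists (models) of `model_fit`s.
#' @return Data.frame: `trait`, `model`, `aicc`, `delta_aicc`, `best`
#'   (lowest AICc per trait; exact ties all flagged, with a message).
#' @export
model_table <- function(fits) {
  rows <- do.call(rbind, lapply(names(fits), function(tn) {
    data.frame(trait = tn, model = names(fits[[tn]]),
               aicc = vapply(fits[[tn]], `[[`, numeric(1), "aicc"),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows$delta_aicc <- stats::ave(rows$aicc, rows$trait, FUN = function(a) a - min(a))
  rows$best <- rows$delta_aicc == 0
  for (tn in unique(rows$trait)) {
    if (sum(rows$best[rows$trait == tn]) > 1) {
      message("AICc tie for trait '", tn, "'")
    }
  }
  rows
}
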