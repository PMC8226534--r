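#' @title Synthetic-data generators
#' @description
#' Seeded generators for every input the analysis pipeline consumes: trees,
#' discrete regime histories, continuous traits under BM / lambda-BM /
#' multi-regime OU, per-sample nectar sugar masses, and Poisson visitation
#' records. Each generator is a pure function of its arguments and seed.
#' @name synthetic_data
NULL

#' Simulate a birth-death tree rescaled to unit depth
#'
#' Yule by default (`death = 0`). The tree is conditioned on `n_tips` extant
#' tips, made ultrametric by construction, and rescaled so the root-to-tip
#' depth is 1, which standardizes the interpretation of `alpha` and `sigma2`
#' across simulated trees.
#'
#' @param n_tips Number of tips (>= 4).
#' @param birth,death Speciation and extinction rates.
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object with tips `t1..tn` and depth 1.
#' @export
#' @examples
#' tr <- simulate_tree(16, seed = 1)
#' max(node_depth_range(tr))
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = 1L) {
  stopifnot(n_tips >= 4, birth > death, death >= 0)
  tr <- with_seed(seed, ape::rphylo(n_tips, birth = birth, death = death))
  depth <- max(node_depths(tr)[seq_len(n_tips)])
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Root-to-tip depth range of a tree
#'
#' @param tree A `phylo` object.
#' @return Numeric length-2 vector (min, max tip depth).
#' @export
node_depth_range <- function(tree) {
  range(node_depths(tree)[seq_along(tree$tip.label)])
}

#' Simulate a regime history forward under an Mk model
#'
#' Gillespie simulation of the continuous-time Markov chain along every
#' branch, from a root state down the tree.
#'
#' @param tree A `phylo` object.
#' @param Q Transition rate matrix with regime dimnames (or a single rate
#'   for an equal-rates model over `states`).
#' @param states Regime labels (needed when `Q` is a scalar rate).
#' @param root_state Regime at the root (default: first state).
#' @param seed Integer seed.
#' @return A `regime_painting` (ground-truth history plus tip states).
#' @export
simulate_regimes <- function(tree, Q, states = colnames(Q),
                             root_state = states[1], seed = 1L) {
  tree <- read_phylogeny(tree)
  if (is.null(dim(Q))) {
    Q <- mk_Q(Q, states, "ER")
  }
  states <- colnames(Q)
  stopifnot(root_state %in% states)
  n <- length(tree$tip.label)
  with_seed(seed, {
    node_state <- integer(max(tree$edge))
    node_state[n + 1L] <- match(root_state, states)
    segs <- vector("list", nrow(tree$edge))
    for (e in rev(ape::postorder(tree))) {
      a <- node_state[tree$edge[e, 1]]
      path <- forward_ctmc(a, tree$edge.length[e], Q, states)
      segs[[e]] <- merge_segments(path$segments)
      node_state[tree$edge[e, 2]] <- path$end
    }
    regime_painting(tree, segs,
                    stats::setNames(states[node_state[seq_len(n)]],
                                    tree$tip.label),
                    root_state)
  })
}

#' Simulate a continuous trait on a tree
#'
#' `"BM"`: multivariate normal with covariance `sigma2 * C` around `x0`.
#' `"lambdaBM"`: Brownian motion on the lambda-transformed covariance
#' (off-diagonals multiplied by `lambda`). `"OU"`: branch-wise
#' Ornstein-Uhlenbeck transition sampling that respects a regime painting
#' (`x_child ~ N(x e^(-a dt) + theta_r (1 - e^(-a dt)),
#' sigma2 (1 - e^(-2 a dt)) / (2 a))`), with the root drawn from the
#' stationary distribution of its regime by default.
#'
#' @param tree A `phylo` object.
#' @param model `"BM"`, `"lambdaBM"`, or `"OU"`.
#' @param params List: `sigma2`; `x0` (BM root value, default 0); `lambda`
#'   (lambdaBM); `alpha` and named `theta` plus optionally
#'   `root = "stationary"` or a number (OU).
#' @param painting Regime painting (OU with multiple optima); default single
#'   regime named as `names(theta)[1]`.
#' @param seed Integer seed.
#' @return Named trait vector over tips.
#' @export
simulate_trait <- function(tree, model = c("BM", "lambdaBM", "OU"), params,
                           painting = NULL, seed = 1L) {
  model <- match.arg(model)
  tree <- read_phylogeny(tree)
  n <- length(tree$tip.label)
  if (model %in% c("BM", "lambdaBM")) {
    C <- vcv_matrix(tree)
    if (model == "lambdaBM") {
      lam <- params$lambda
      Cl <- lam * C
      diag(Cl) <- diag(C)
      C <- Cl
    }
    x0 <- if (is.null(params$x0)) 0 else params$x0
    L <- t(chol(params$sigma2 * C))
    return(with_seed(seed, stats::setNames(
      as.numeric(x0 + L %*% stats::rnorm(n)), tree$tip.label)))
  }
  if (is.null(painting)) painting <- uniform_painting(tree, names(params$theta)[1])
  alpha <- params$alpha
  sigma2 <- params$sigma2
  theta <- params$theta
  with_seed(seed, {
    vals <- numeric(max(tree$edge))
    root_regime <- painting$root_state
    vals[n + 1L] <- if (is.null(params$root) || identical(params$root, "stationary")) {
      stats::rnorm(1, theta[[root_regime]], sqrt(sigma2 / (2 * alpha)))
    } else {
      params$root
    }
    for (e in rev(ape::postorder(tree))) {
      x <- vals[tree$edge[e, 1]]
      seg <- painting$segments[[e]]
      for (s in seq_len(nrow(seg))) {
        dt <- seg$length[s]
        th <- theta[[seg$regime[s]]]
        if (dt > 0) {
          m <- x * exp(-alpha * dt) + th * (1 - exp(-alpha * dt))
          v <- sigma2 * (-expm1(-2 * alpha * dt)) / (2 * alpha)
          x <- stats::rnorm(1, m, sqrt(v))
        }
      }
      vals[tree$edge[e, 2]] <- x
    }
    stats::setNames(vals[seq_len(n)], tree$tip.label)
  })
}

#' Simulate per-sample nectar sugar masses
#'
#' Per species, total sugar per sample is log-normal (matching the requested
#' mean and coefficient of variation) and the sugar split is Dirichlet around
#' the species mean proportions with concentration `conc` (larger = less
#' sample-to-sample variation). A modeling convenience: real nectar data make
#' no particular distributional claim.
#'
#' @param spec Data.frame: `species`, `n_samples`, `prop_sucrose`,
#'   `prop_glucose`, `prop_fructose`, `mean_amount` (ug/flower/24 h).
#' @param conc Dirichlet concentration (default 50).
#' @param amount_cv Coefficient of variation of sample totals (default 0.5).
#' @param seed Integer seed.
#' @return A `nectar_samples` data.frame (`species`, `sucrose_ug`,
#'   `glucose_ug`, `fructose_ug`).
#' @export
simulate_nectar_samples <- function(spec, conc = 50, amount_cv = 0.5, seed = 1L) {
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(spec)), function(i) {
      m <- spec$n_samples[i]
      mu <- spec$mean_amount[i]
      sdlog <- sqrt(log(1 + amount_cv^2))
      tot <- stats::rlnorm(m, log(mu) - sdlog^2 / 2, sdlog)
      a <- conc * c(spec$prop_sucrose[i], spec$prop_glucose[i], spec$prop_fructose[i])
      g <- matrix(stats::rgamma(3 * m, shape = rep(a, each = m)), m, 3)
      p <- g / rowSums(g)
      data.frame(species = spec$species[i], sucrose_ug = tot * p[, 1],
                 glucose_ug = tot * p[, 2], fructose_ug = tot * p[, 3],
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("nectar_samples", "data.frame")
    out
  })
}

#' Simulate flower-visitation records
#'
#' Each species is observed on `n_plants` plant individuals with `n_flowers`
#' flowers for `hours` hours each; per group, visits are Poisson with mean
#' `rate * flower-hours`.
#'
#' @param species Character vector of species.
#' @param group_rates Either a named numeric vector (same rates for every
#'   species) or a matrix species x groups of visits per flower-hour.
#' @param n_plants,n_flowers,hours Observation design (defaults 5, 1, 24).
#' @param seed Integer seed.
#' @return A visitation data.frame as read by [load_visitation()].
#' @export
simulate_visitation <- function(species, group_rates, n_plants = 5,
                                n_flowers = 1, hours = 24, seed = 1L) {
  if (is.null(dim(group_rates))) {
    group_rates <- matrix(group_rates, nrow = length(species),
                          ncol = length(group_rates), byrow = TRUE,
                          dimnames = list(species, names(group_rates)))
  }
  with_seed(seed, {
    rows <- list()
    for (s in seq_along(species)) {
      for (pl in seq_len(n_plants)) {
        for (g in colnames(group_rates)) {
          rows[[length(rows) + 1]] <- data.frame(
            species = species[s], plant_individual = paste0("plant", pl),
            n_flowers = n_flowers, observation_hours = hours, group = g,
            visits = stats::rpois(1, group_rates[s, g] * n_flowers * hours),
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}
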