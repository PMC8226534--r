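#' @title Simulation-based phylogenetic ANOVA / MANOVA
#' @description
#' Group differences among species are tested with the classical F (or
#' Wilks' Lambda) statistic, but its null distribution is generated by
#' simulating trait evolution under Brownian motion on the phylogeny with
#' the rate (matrix) estimated from the data, keeping the observed group
#' labels fixed. This corrects the test for phylogenetic non-independence
#' of species.
#' @name comparative_tests
NULL

anova_f <- function(x, groups) {
  n <- length(x)
  k <- nlevels(groups)
  gm <- tapply(x, groups, mean)
  ssb <- sum(tabulate(groups) * (gm - mean(x))^2)
  ssw <- sum((x - gm[groups])^2)
  ((ssb / (k - 1)) / (ssw / (n - k)))
}

check_groups <- function(tree, groups) {
  if (is.null(names(groups))) {
    if (length(groups) != length(tree$tip.label))
      stop("groups length does not match tip count", call. = FALSE)
    names(groups) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(groups))
  if (length(miss)) stop("group missing for tips: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  g <- factor(groups[tree$tip.label])
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs >= 2 species", call. = FALSE)
  g
}

# ML Brownian rate given the phylogenetic covariance (GLS mean, divisor n)
bm_rate_ml <- function(x, C) {
  n <- length(x)
  ch <- chol(C)
  Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- sum(Vi_x) / sum(Vi_1)
  r <- x - a
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  list(sigma2 = sum(r * Vi_r) / n, mean = a)
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' The observed one-way F is compared to F statistics recomputed on `n_sim`
#' data sets simulated under Brownian motion on the tree (rate = ML estimate
#' from the data, GLS mean) with the same group labels;
#' `p_phylogenetic = (1 + #\{F_sim >= F_obs\}) / (n_sim + 1)`. Games-Howell
#' post hoc comparisons on the species values accompany the omnibus test.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector.
#' @param groups Named group labels (names = tip labels).
#' @param n_sim Number of Brownian null simulations (default 1000).
#' @param seed Integer seed.
#' @return List of class `group_comparison`: `statistic_name` ("F"),
#'   `observed`, `df`, `p_standard`, `p_phylogenetic`, `n_sim`, `sigma2`,
#'   `posthoc` (Games-Howell table).
#' @export
phylo_anova <- function(tree, x, groups, n_sim = 1000, seed = 1L) {
  stopifnot(n_sim >= 1)
  tree <- read_phylogeny(tree)
  x <- check_trait(tree, x)
  g <- check_groups(tree, groups)
  n <- length(x)
  k <- nlevels(g)
  C <- vcv_matrix(tree)
  fit <- bm_rate_ml(x, C)
  f_obs <- anova_f(x, g)
  L <- t(chol(fit$sigma2 * C))
  f_sim <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n * n_sim), n, n_sim)
    Y <- fit$mean + L %*% Z
    apply(Y, 2, anova_f, groups = g)
  })
  out <- list(
    statistic_name = "F", observed = f_obs, df = c(k - 1, n - k),
    p_standard = stats::pf(f_obs, k - 1, n - k, lower.tail = FALSE),
    p_phylogenetic = (1 + sum(f_sim >= f_obs)) / (n_sim + 1),
    n_sim = n_sim, sigma2 = fit$sigma2,
    posthoc = games_howell(x, g)
  )
  class(out) <- "group_comparison"
  out
}

wilks_lambda <- function(X, groups) {
  Xc <- scale(X, scale = FALSE)
  Tm <- crossprod(Xc)
  gm <- vapply(seq_len(ncol(X)),
               function(j) tapply(X[, j], groups, mean),
               numeric(nlevels(groups)))
  Wm <- crossprod(X - gm[as.integer(groups), , drop = FALSE])
  det(Wm) / det(Tm)
}

# Wilks' Lambda -> F approximation (Rao), for the standard p-value
wilks_f_p <- function(lambda, n, p, k) {
  vh <- k - 1
  ve <- n - k
  s <- sqrt((p^2 * vh^2 - 4) / (p^2 + vh^2 - 5))
  if (!is.finite(s) || s == 0) s <- 1
  df1 <- p * vh
  df2 <- s * (ve + vh - (p + vh + 1) / 2) - (p * vh - 2) / 2
  lam_s <- lambda^(1 / s)
  f <- (1 - lam_s) / lam_s * df2 / df1
  stats::pf(f, df1, df2, lower.tail = FALSE)
}

# evolutionary rate matrix from phylogenetically independent contrasts
pic_rate_matrix <- function(tree, X) {
  U <- apply(X, 2, function(col) ape::pic(col, tree))
  crossprod(U) / nrow(U)
}

#' Phylogenetic MANOVA by multivariate Brownian simulation
#'
#' Observed Wilks' Lambda versus Lambda recomputed on data simulated under
#' multivariate Brownian motion with the evolutionary rate matrix estimated
#' from phylogenetically independent contrasts; smaller Lambda means stronger
#' group separation, so
#' `p_phylogenetic = (1 + #\{Lambda_sim <= Lambda_obs\}) / (n_sim + 1)`.
#'
#' Compositional trait sets (columns summing to a constant, e.g. the three
#' sugar proportions) are rank-deficient; with `preprocess = "auto"` the last
#' column is dropped (completing the composition) and a message records it.
#' `preprocess = "ilr"` maps a 3-part composition to 2 isometric log-ratio
#' coordinates instead (requires strictly positive parts).
#'
#' @param tree A `phylo` object.
#' @param X Numeric matrix, rows = tips (rownames = tip labels).
#' @param groups Named group labels.
#' @param n_sim Number of null simulations (default 1000).
#' @param seed Integer seed.
#' @param preprocess `"auto"` (default), `"none"`, or `"ilr"`.
#' @return List of class `group_comparison` with `statistic_name`
#'   ("Wilks_Lambda"), `observed`, `p_standard`, `p_phylogenetic`, `n_sim`,
#'   `columns_used`, `rate_matrix`.
#' @export
phylo_manova <- function(tree, X, groups, n_sim = 1000, seed = 1L,
                         preprocess = c("auto", "none", "ilr")) {
  preprocess <- match.arg(preprocess)
  stopifnot(n_sim >= 1)
  tree <- read_phylogeny(tree)
  X <- as.matrix(X)
  if (is.null(rownames(X))) {
    stopifnot(nrow(X) == length(tree$tip.label))
    rownames(X) <- tree$tip.label
  }
  X <- X[tree$tip.label, , drop = FALSE]
  g <- check_groups(tree, groups)
  if (preprocess == "ilr") {
    X <- ilr_transform(X)
  } else if (preprocess == "auto") {
    rs <- rowSums(X)
    if (max(rs) - min(rs) < 1e-2 * mean(abs(rs))) {
      message("compositional trait set detected; dropping column '",
              colnames(X)[ncol(X)], "'")
      X <- X[, -ncol(X), drop = FALSE]
    }
  }
  if (qr(scale(X, scale = FALSE))$rank < ncol(X)) {
    stop("trait matrix is rank deficient after preprocessing", call. = FALSE)
  }
  n <- nrow(X)
  p <- ncol(X)
  k <- nlevels(g)
  lam_obs <- wilks_lambda(X, g)
  R <- pic_rate_matrix(tree, X)
  C <- vcv_matrix(tree)
  L <- t(chol(C))
  B <- chol(R)
  lam_sim <- with_seed(seed, vapply(seq_len(n_sim), function(i) {
    Z <- matrix(stats::rnorm(n * p), n, p)
    wilks_lambda(L %*% Z %*% B, g)
  }, numeric(1)))
  out <- list(
    statistic_name = "Wilks_Lambda", observed = lam_obs,
    p_standard = wilks_f_p(lam_obs, n, p, k),
    p_phylogenetic = (1 + sum(lam_sim <= lam_obs)) / (n_sim + 1),
    n_sim = n_sim, columns_used = colnames(X), rate_matrix = R
  )
  class(out) <- "group_comparison"
  out
}

#' Isometric log-ratio coordinates of a composition
#'
#' Standard ilr with the Helmert-like default basis; rows must be strictly
#' positive compositions.
#'
#' @param X Matrix of D-part compositions (rows sum to a constant).
#' @return Matrix with D-1 ilr coordinates.
#' @export
ilr_transform <- function(X) {
  if (any(X <= 0)) stop("ilr requires strictly positive parts", call. = FALSE)
  D <- ncol(X)
  lx <- log(X)
  out <- sapply(seq_len(D - 1), function(i) {
    sqrt(i / (i + 1)) * (rowMeans(lx[, seq_len(i), drop = FALSE]) - lx[, i + 1])
  })
  out <- matrix(out, nrow = nrow(X))
  colnames(out) <- paste0("ilr", seq_len(D - 1))
  rownames(out) <- rownames(X)
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s = %.4g, p(standard) = %.4g, p(phylogenetic) = %.4g (%d simulations)\n",
              x$statistic_name, x$observed, x$p_standard, x$p_phylogenetic, x$n_sim))
  invisible(x)
}

#' Games-Howell post hoc pairwise comparisons
#'
#' Welch-type pairwise t statistics with Satterthwaite degrees of freedom,
#' referred to the studentized-range distribution with `k` means
#' (`q = |t| * sqrt(2)`). Robust to unequal variances and group sizes; no
#' phylogenetic correction (species values are treated as observations).
#'
#' @param x Numeric response vector.
#' @param groups Group labels (factor or character), same length as `x`.
#' @return Data.frame: `group_i`, `group_j`, `diff`, `t`, `df`, `p_value`.
#' @export
#' @examples
#' games_howell(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
games_howell <- function(x, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2) stop("need >= 2 groups", call. = FALSE)
  ns <- tapply(x, g, length)
  if (any(ns < 2)) stop("every group needs >= 2 observations", call. = FALSE)
  ms <- tapply(x, g, mean)
  vs <- tapply(x, g, stats::var)
  if (any(vs == 0)) stop("zero-variance group", call. = FALSE)
  pairs <- utils::combn(levels(g), 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se2 <- vs[i] / ns[i] + vs[j] / ns[j]
    t_stat <- (ms[i] - ms[j]) / sqrt(se2)
    df <- se2^2 / ((vs[i] / ns[i])^2 / (ns[i] - 1) + (vs[j] / ns[j])^2 / (ns[j] - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    c(diff = unname(ms[i] - ms[j]), t = unname(t_stat), df = unname(df),
      p_value = unname(p))
  })
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ], t(res),
             stringsAsFactors = FALSE)
}
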