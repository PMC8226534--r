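#' @title Phylogenetic signal statistics
#' @description
#' Four tree-level indices of phylogenetic signal (Abouheif's Cmean, Moran's
#' I, Blomberg's K, Pagel's lambda) plus per-tip local Moran's I, each with
#' its significance test. Autocorrelation indices share the quadratic-form
#' kernel `I = z' W z / z' z` with row-normalized weights; their p-values
#' come from seeded tip-value permutations with the
#' `(1 + exceedances) / (n_perm + 1)` convention. K uses a permutation test
#' of the K statistic itself; lambda uses a likelihood-ratio test against
#' `lambda = 0`.
#' @name signal_stats
NULL

new_signal_result <- function(trait, method, statistic, p_value, n, extra = list()) {
  out <- c(list(trait = trait, method = method, statistic = statistic,
                p_value = p_value, n = n), extra)
  class(out) <- "signal_result"
  out
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g, p = %.4g (n = %d)%s\n",
              x$trait, x$method, x$statistic, x$p_value, x$n,
              if (isTRUE(x$degenerate)) " [degenerate trait]" else ""))
  invisible(x)
}

# readable label for result objects when none is supplied
trait_label <- function(expr) {
  lab <- paste(deparse(expr), collapse = "")
  if (nchar(lab) > 32) "trait" else lab
}

check_trait <- function(tree, x) {
  if (is.null(names(x))) {
    if (length(x) != length(tree$tip.label))
      stop("trait length does not match tip count", call. = FALSE)
    names(x) <- tree$tip.label
  }
  miss <- setdiff(tree$tip.label, names(x))
  if (length(miss)) stop("trait missing for tips: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  x <- x[tree$tip.label]
  if (anyNA(x)) stop("NA trait values", call. = FALSE)
  x
}

perm_p <- function(obs, perms, alternative) {
  n_perm <- length(perms)
  p_gr <- (1 + sum(perms >= obs)) / (n_perm + 1)
  p_ls <- (1 + sum(perms <= obs)) / (n_perm + 1)
  switch(alternative,
         greater = p_gr,
         less = p_ls,
         two.sided = min(1, 2 * min(p_gr, p_ls)))
}

autocorr_index <- function(x, W) {
  z <- x - mean(x)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  as.numeric(crossprod(z, W %*% z) / denom)
}

autocorr_test <- function(tree, x, W, method, n_perm, seed, alternative, trait) {
  x <- check_trait(tree, x)
  n <- length(x)
  obs <- autocorr_index(x, W)
  if (is.na(obs)) {
    return(new_signal_result(trait, method, NA_real_, NA_real_, n,
                             list(degenerate = TRUE)))
  }
  perms <- with_seed(seed, replicate(n_perm, autocorr_index(sample(x), W)))
  new_signal_result(trait, method, obs, perm_p(obs, perms, alternative), n,
                    list(n_perm = n_perm, expectation = -1 / (n - 1),
                         alternative = alternative))
}

#' Moran's I phylogenetic autocorrelation
#'
#' `I = z' W z / z' z` with inverse-patristic-distance, row-normalized
#' weights; expectation under random tip permutation is `-1/(n-1)`.
#'
#' @param tree A `phylo` object.
#' @param x Named trait vector (names = tip labels).
#' @param n_perm Number of seeded permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @param alternative `"greater"` (default; positive signal), `"less"`, or
#'   `"two.sided"`.
#' @param trait Label used in result tables.
#' @return A `signal_result`.
#' @export
moran_i <- function(tree, x, n_perm = 999, seed = 1L,
                    alternative = c("greater", "less", "two.sided"),
                    trait = trait_label(substitute(x))) {
  alternative <- match.arg(alternative)
  tree <- read_phylogeny(tree)
  autocorr_test(tree, x, inverse_distance_weights(tree), "moran_i",
                n_perm, seed, alternative, trait)
}

#' Abouheif's Cmean
#'
#' Same autocorrelation kernel as [moran_i()] but with the topology-only
#' Abouheif proximity matrix (row-normalized) as weights, so the statistic
#' is invariant to branch-length rescaling.
#'
#' @inheritParams moran_i
#' @return A `signal_result`.
#' @export
abouheif_cmean <- function(tree, x, n_perm = 999, seed = 1L,
                           alternative = c("greater", "less", "two.sided"),
                           trait = trait_label(substitute(x))) {
  alternative <- match.arg(alternative)
  tree <- read_phylogeny(tree)
  autocorr_test(tree, x, row_normalize(abouheif_proximity(tree)),
                "abouheif_cmean", n_perm, seed, alternative, trait)
}

#' Local Moran's I per tip
#'
#' `I_i = z_i * sum_j W[i,j] z_j / (sum_k z_k^2 / n)`; under row-normalized
#' weights the mean of the local values equals the global Moran's I. The
#' per-tip p-value uses conditional permutation: tip i's value is held fixed
#' while the remaining values are shuffled over the other tips. Tips with
#' `p < alpha` are flagged as hotspots of local trait autocorrelation.
#'
#' @inheritParams moran_i
#' @param alpha Hotspot flagging level (default 0.05).
#' @return Data.frame: `tip`, `local_i`, `p_value`, `hotspot`.
#' @export
local_moran_i <- function(tree, x, n_perm = 999, seed = 1L,
                          alternative = c("greater", "less", "two.sided"),
                          alpha = 0.05) {
  alternative <- match.arg(alternative)
  tree <- read_phylogeny(tree)
  x <- check_trait(tree, x)
  W <- inverse_distance_weights(tree)
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  if (m2 == 0) stop("constant trait: local Moran's I undefined", call. = FALSE)
  lag <- as.numeric(W %*% z)
  obs <- z * lag / m2
  p <- with_seed(seed, vapply(seq_len(n), function(i) {
    others <- z[-i]
    perms <- replicate(n_perm, {
      zp <- z
      zp[-i] <- sample(others)
      z[i] * sum(W[i, ] * zp) / m2
    })
    perm_p(obs[i], perms, alternative)
  }, numeric(1)))
  data.frame(tip = tree$tip.label, local_i = unname(obs), p_value = p,
             hotspot = p < alpha, stringsAsFactors = FALSE)
}

#' Blomberg's K
#'
#' Ratio of the observed mean squared error of tip values around the
#' phylogenetic (GLS) mean to the GLS mean squared error, scaled by its
#' Brownian-motion expectation so that K = 1 under Brownian evolution on the
#' tree. The test permutes tip values and recomputes K.
#'
#' @inheritParams moran_i
#' @return A `signal_result`.
#' @export
blomberg_k <- function(tree, x, n_perm = 999, seed = 1L,
                       alternative = c("greater", "less", "two.sided"),
                       trait = trait_label(substitute(x))) {
  alternative <- match.arg(alternative)
  tree <- read_phylogeny(tree)
  x <- check_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need >= 4 tips", call. = FALSE)
  C <- vcv_matrix(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("singular phylogenetic covariance matrix", call. = FALSE))
  ones <- rep(1, n)
  Cinv1 <- Cinv %*% ones
  s1 <- sum(Cinv1)                        # 1' C^-1 1
  expect <- (sum(diag(C)) - n / s1) / (n - 1)
  k_stat <- function(v) {
    a <- sum(Cinv1 * v) / s1
    r <- v - a
    mse0 <- sum(r^2) / (n - 1)
    mse <- as.numeric(crossprod(r, Cinv %*% r)) / (n - 1)
    (mse0 / mse) / expect
  }
  if (stats::sd(x) == 0) {
    return(new_signal_result(trait, "blomberg_k", NA_real_, NA_real_, n,
                             list(degenerate = TRUE)))
  }
  obs <- k_stat(x)
  perms <- with_seed(seed, replicate(n_perm, k_stat(sample(x))))
  new_signal_result(trait, "blomberg_k", obs, perm_p(obs, perms, alternative),
                    n, list(n_perm = n_perm, alternative = alternative))
}

# profile log-likelihood of the lambda model at a given lambda
lambda_loglik <- function(lam, x, C) {
  n <- length(x)
  V <- lam * C
  diag(V) <- diag(C)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-1e12)
  logdet <- 2 * sum(log(diag(ch)))
  Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  a <- sum(Vi_x) / sum(Vi_1)
  r <- x - a
  Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Vi_r) / n
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda
#'
#' Maximum-likelihood estimate of the multiplier of the off-diagonal
#' phylogenetic covariances, searched over `[0, 1]`; `lambda = 0` is an iid
#' (star-tree) model, `lambda = 1` plain Brownian motion. The p-value is a
#' likelihood-ratio test of the ML lambda against `lambda = 0` on one degree
#' of freedom.
#'
#' @inheritParams moran_i
#' @return A `signal_result` with extra fields `loglik`, `loglik0`, `sigma2`.
#' @export
pagel_lambda <- function(tree, x, trait = trait_label(substitute(x))) {
  tree <- read_phylogeny(tree)
  x <- check_trait(tree, x)
  n <- length(x)
  if (n < 4) stop("need >= 4 tips", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(new_signal_result(trait, "pagel_lambda", NA_real_, NA_real_, n,
                             list(degenerate = TRUE)))
  }
  C <- vcv_matrix(tree)
  opt <- stats::optimize(lambda_loglik, c(0, 1), x = x, C = C, maximum = TRUE,
                         tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective),
                c(0, lambda_loglik(0, x, C)),
                c(1, lambda_loglik(1, x, C)))
  best <- cand[which.max(cand[, 2]), ]
  lnl0 <- cand[2, 2]
  lrt <- max(0, 2 * (best[2] - lnl0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  new_signal_result(trait, "pagel_lambda", best[1], p, n,
                    list(loglik = best[2], loglik0 = lnl0, lrt = lrt))
}

#' Significance stars for report tables
#'
#' `**` for p < 0.01, `*` for p < 0.05, dagger for p < 0.1, else empty.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
signif_stars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.1] <- "†"
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out
}

#' Signal-index table across traits
#'
#' Runs all four indices on each column of a trait matrix and assembles the
#' index-by-trait grid with significance stars.
#'
#' @param tree A `phylo` object.
#' @param traits Numeric matrix or data.frame, rows = tips (rownames = tip
#'   labels), columns = traits.
#' @param n_perm,seed Passed to the permutation tests.
#' @return Data.frame: `trait`, `method`, `statistic`, `p_value`, `stars`.
#' @export
phylo_signal_table <- function(tree, traits, n_perm = 999, seed = 1L) {
  tree <- read_phylogeny(tree)
  traits <- as.matrix(traits)
  methods <- list(abouheif_cmean = abouheif_cmean, moran_i = moran_i,
                  blomberg_k = blomberg_k,
                  pagel_lambda = function(tree, x, n_perm, seed, trait)
                    pagel_lambda(tree, x, trait = trait))
  rows <- list()
  for (tn in colnames(traits)) {
    x <- stats::setNames(traits[, tn], rownames(traits))
    for (mn in names(methods)) {
      res <- if (mn == "pagel_lambda") {
        pagel_lambda(tree, x, trait = tn)
      } else {
        methods[[mn]](tree, x, n_perm = n_perm, seed = seed, trait = tn)
      }
      rows[[length(rows) + 1]] <- data.frame(
        trait = tn, method = mn, statistic = res$statistic,
        p_value = res$p_value, stars = signif_stars(res$p_value),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
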