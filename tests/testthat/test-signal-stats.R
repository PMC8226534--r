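test_that("Blomberg's K is exactly 1 on star trees and matches phytools", {
  skip_if_not_installed("phytools")
  star <- star_tree(8)
  x <- stats::setNames(rnorm(8), star$tip.label)
  expect_equal(blomberg_k(star, x, n_perm = 19, seed = 1)$statistic, 1,
               tolerance = 1e-10)
  for (seed in 1:3) {
    tr <- simulate_tree(24, seed = seed)
    y <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = seed + 100)
    mine <- blomberg_k(tr, y, n_perm = 19, seed = 1)$statistic
    ref <- as.numeric(phytools::phylosig(tr, y, method = "K"))
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("K permutation p is small for clustered traits, large for noise", {
  tr <- simulate_tree(40, seed = 6)
  y <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 7)
  res_bm <- blomberg_k(tr, y, n_perm = 199, seed = 2)
  noise <- stats::setNames(rnorm(40), tr$tip.label)
  res_no <- blomberg_k(tr, noise, n_perm = 199, seed = 2)
  expect_lt(res_bm$p_value, 0.05)
  expect_gt(res_no$p_value, 0.05)
  # constant trait is flagged, not an error
  const <- stats::setNames(rep(1, 40), tr$tip.label)
  expect_true(blomberg_k(tr, const, n_perm = 19, seed = 1)$degenerate)
})

test_that("Pagel's lambda profile likelihood agrees with phytools", {
  skip_if_not_installed("phytools")
  for (seed in 1:3) {
    tr <- simulate_tree(32, seed = seed + 20)
    y <- simulate_trait(tr, "lambdaBM", list(sigma2 = 1, lambda = 0.6),
                        seed = seed + 200)
    mine <- pagel_lambda(tr, y)
    ref <- phytools::phylosig(tr, y, method = "lambda")
    # phytools searches lambda slightly beyond 1; compare where comparable
    if (ref$lambda <= 1) {
      expect_equal(mine$statistic, ref$lambda, tolerance = 1e-3)
      expect_equal(mine$loglik, ref$logL, tolerance = 1e-5)
    } else {
      expect_equal(mine$statistic, 1, tolerance = 1e-6)
    }
  }
})

test_that("lambda = 0 log-likelihood reduces to the iid normal likelihood", {
  tr <- simulate_tree(16, seed = 9)
  x <- simulate_trait(tr, "BM", list(sigma2 = 2), seed = 10)
  C <- vcv_matrix(tr)
  res <- pagel_lambda(tr, x)
  # direct iid likelihood on diagonal C with GLS mean and ML variance
  d <- diag(C)
  w <- 1 / d
  a <- sum(w * x) / sum(w)
  s2 <- sum((x - a)^2 / d) / length(x)
  lnl0 <- sum(dnorm(x, a, sqrt(s2 * d), log = TRUE))
  expect_equal(res$loglik0, lnl0, tolerance = 1e-8)
})

test_that("Moran's I equals ape's implementation under identical weights", {
  tr <- simulate_tree(20, seed = 13)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 14)
  mine <- moran_i(tr, x, n_perm = 99, seed = 1)
  ref <- ape::Moran.I(as.numeric(x), inverse_distance_weights(tr))
  expect_equal(mine$statistic, ref$observed, tolerance = 1e-10)
  expect_equal(mine$expectation, ref$expected)
  # clustered trait (one clade shifted): positive I with small p
  cl <- read_phylogeny("(((a:1,b:1):1,(c:1,d:1):1):2,((e:1,f:1):1,(g:1,h:1):1):2);")
  xc <- stats::setNames(c(8, 8.5, 9, 8.2, 0.1, -0.2, 0.3, 0), cl$tip.label)
  rc <- moran_i(cl, xc, n_perm = 199, seed = 3)
  expect_gt(rc$statistic, 0)
  expect_lt(rc$p_value, 0.05)
  # identical trait values: flagged degenerate
  expect_true(moran_i(cl, stats::setNames(rep(2, 8), cl$tip.label),
                      n_perm = 9, seed = 1)$degenerate)
})

test_that("local Moran's I averages to the global statistic and finds hotspots", {
  tr <- simulate_tree(24, seed = 16)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 17)
  loc <- local_moran_i(tr, x, n_perm = 49, seed = 1)
  glob <- moran_i(tr, x, n_perm = 49, seed = 1)
  expect_equal(mean(loc$local_i), glob$statistic, tolerance = 1e-10)
  # a tip at the mean of the others has z = 0, hence zero local I
  x2 <- x; x2[5] <- mean(x[-5])
  loc2 <- local_moran_i(tr, x2, n_perm = 9, seed = 1)
  expect_equal(loc2$local_i[5], 0, tolerance = 1e-8)
  # a coherent shifted clade against heterogeneous background: flags and the
  # largest local values concentrate in that clade
  cl <- read_phylogeny(paste0("(((a:1,b:1):1,(c:1,d:1):1):3,",
    "(((e:1,f:1):1,(g:1,h:1):1):1,((i:1,j:1):1,(k:1,l:1):1):1):2);"))
  set.seed(5)
  xs <- stats::setNames(c(10 + rnorm(4, 0, 0.2), rnorm(8, 0, 3)), cl$tip.label)
  hot <- local_moran_i(cl, xs, n_perm = 199, seed = 4)
  clade <- hot$tip %in% c("a", "b", "c", "d")
  expect_true(all(hot$hotspot[clade]))
  expect_gt(mean(hot$local_i[clade]), mean(hot$local_i[!clade]))
})

test_that("Abouheif's Cmean shares the autocorrelation kernel and ignores scale", {
  tr <- simulate_tree(20, seed = 21)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 22)
  res <- abouheif_cmean(tr, x, n_perm = 99, seed = 1)
  # same kernel with A substituted for W
  A <- row_normalize(abouheif_proximity(tr))
  z <- x - mean(x)
  expect_equal(res$statistic, as.numeric(t(z) %*% A %*% z / sum(z^2)),
               tolerance = 1e-12)
  # branch-length invariance
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 12
  expect_equal(abouheif_cmean(tr2, x, n_perm = 9, seed = 1)$statistic,
               res$statistic)
})

test_that("signal indices are invariant to affine trait transformations", {
  tr <- simulate_tree(16, seed = 25)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 26)
  y <- 3.2 * x - 7
  for (f in list(moran_i, abouheif_cmean, blomberg_k)) {
    expect_equal(f(tr, y, n_perm = 49, seed = 5)$statistic,
                 f(tr, x, n_perm = 49, seed = 5)$statistic, tolerance = 1e-9)
  }
  expect_equal(pagel_lambda(tr, y)$statistic, pagel_lambda(tr, x)$statistic,
               tolerance = 1e-5)
})

test_that("permutation tests follow the add-one convention and are seeded", {
  tr <- simulate_tree(12, seed = 31)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 32)
  r1 <- moran_i(tr, x, n_perm = 99, seed = 7)
  r2 <- moran_i(tr, x, n_perm = 99, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(r1$p_value >= 1 / 100 && r1$p_value <= 1)
  # p is a multiple of 1/(n_perm + 1)
  expect_equal(r1$p_value * 100, round(r1$p_value * 100))
})

test_that("signal table covers all four indices with stars", {
  tr <- simulate_tree(16, seed = 41)
  tm <- cbind(t1 = simulate_trait(tr, "BM", list(sigma2 = 1), seed = 42),
              t2 = stats::setNames(rnorm(16), tr$tip.label))
  tab <- phylo_signal_table(tr, tm, n_perm = 49, seed = 1)
  expect_equal(nrow(tab), 8)
  expect_setequal(unique(tab$method),
                  c("abouheif_cmean", "moran_i", "blomberg_k", "pagel_lambda"))
  expect_equal(signif_stars(c(0.2, 0.07, 0.03, 0.005)), c("", "†", "*", "**"))
})
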