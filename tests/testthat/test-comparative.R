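test_that("observed F matches classical ANOVA and phytools' phylANOVA", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(32, seed = 3)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 4)
  g <- stats::setNames(rep(c("a", "b", "c", "d"), each = 8), tr$tip.label)
  res <- phylo_anova(tr, x, g, n_sim = 200, seed = 2)
  f_aov <- summary(stats::aov(x ~ factor(g[names(x)])))[[1]]$`F value`[1]
  expect_equal(res$observed, f_aov, tolerance = 1e-10)
  ref <- phytools::phylANOVA(tr, g[tr$tip.label], x[tr$tip.label],
                             nsim = 200, posthoc = FALSE)
  expect_equal(res$observed, ref$F, tolerance = 1e-10)
  expect_lt(abs(res$p_phylogenetic - ref$Pf), 0.15)
})

test_that("star tree makes the phylogenetic and standard ANOVA p agree", {
  star <- star_tree(30)
  x <- stats::setNames(c(rnorm(10, 3), rnorm(20, 0)), star$tip.label)
  g <- stats::setNames(rep(c("hi", "lo", "lo2"), each = 10), star$tip.label)
  res <- phylo_anova(star, x, g, n_sim = 2000, seed = 5)
  expect_lt(abs(res$p_phylogenetic - res$p_standard),
            3 * sqrt(0.05 * 0.95 / 2000) + 0.01)
})

test_that("phylogenetic correction raises p for clade-confounded groups", {
  # two clades, groups perfectly aligned with clades, trait purely Brownian
  tr <- read_phylogeny(paste0(
    "((a1:1,a2:1,a3:1,a4:1,a5:1):9,(b1:1,b2:1,b3:1,b4:1,b5:1):9);"))
  tr <- resolve_multichotomies(tr, seed = 1)
  g <- stats::setNames(rep(c("A", "B"), each = 5), tr$tip.label)
  ps <- pp <- numeric(20)
  for (i in 1:20) {
    x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 100 + i)
    r <- phylo_anova(tr, x, g, n_sim = 200, seed = i)
    ps[i] <- r$p_standard; pp[i] <- r$p_phylogenetic
  }
  expect_gt(mean(pp), mean(ps))
  expect_gt(mean(pp > 0.05), 0.7)   # deep-clade split rarely "significant"
})

test_that("p_phylogenetic is invariant to trait rescaling", {
  tr <- simulate_tree(24, seed = 8)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 9)
  g <- stats::setNames(rep(c("a", "b", "c"), each = 8), tr$tip.label)
  r1 <- phylo_anova(tr, x, g, n_sim = 100, seed = 3)
  r2 <- phylo_anova(tr, 100 * x + 4, g, n_sim = 100, seed = 3)
  expect_equal(r1$p_phylogenetic, r2$p_phylogenetic)
  expect_equal(r1$observed, r2$observed, tolerance = 1e-9)
})

test_that("Wilks' Lambda matches stats::manova and pMANOVA detects shifts", {
  tr <- simulate_tree(30, seed = 12)
  g <- stats::setNames(rep(c("a", "b", "c"), each = 10), tr$tip.label)
  X <- cbind(u = simulate_trait(tr, "BM", list(sigma2 = 1), seed = 13),
             v = simulate_trait(tr, "BM", list(sigma2 = 1), seed = 14))
  res <- phylo_manova(tr, X, g, n_sim = 200, seed = 4)
  ref <- summary(stats::manova(X ~ factor(g[rownames(X)])),
                 test = "Wilks")$stats[1, "Wilks"]
  expect_equal(res$observed, unname(ref), tolerance = 1e-10)
  # strong shift on a (resolved) star tree: tiny p
  star <- resolve_multichotomies(star_tree(30), seed = 1)
  Xs <- X; rownames(Xs) <- star$tip.label
  Xs[1:10, ] <- Xs[1:10, ] + 10
  gs <- stats::setNames(g, star$tip.label)
  rs <- phylo_manova(star, Xs, gs, n_sim = 200, seed = 5)
  expect_lt(rs$p_phylogenetic, 0.02)
})

test_that("compositional trait sets are reduced before MANOVA", {
  tr <- simulate_tree(24, seed = 18)
  g <- stats::setNames(rep(c("a", "b"), each = 12), tr$tip.label)
  a <- plogis(simulate_trait(tr, "BM", list(sigma2 = 1), seed = 19))
  b <- (1 - a) * plogis(simulate_trait(tr, "BM", list(sigma2 = 1), seed = 20))
  P <- cbind(p1 = a, p2 = b, p3 = 1 - a - b)
  expect_message(res <- phylo_manova(tr, P, g, n_sim = 50, seed = 1),
                 "compositional")
  expect_equal(res$columns_used, c("p1", "p2"))
  # ilr route gives 2 coordinates and runs
  res2 <- phylo_manova(tr, P, g, n_sim = 50, seed = 1, preprocess = "ilr")
  expect_equal(res2$columns_used, c("ilr1", "ilr2"))
})

test_that("Games-Howell reduces to Tukey under equal n/variances, matches by-hand t", {
  set.seed(44)
  # identical within-group values shifted by constants: variances exactly
  # equal, so the only Tukey/GH difference is Welch vs pooled df
  base <- as.numeric(scale(rnorm(50)))
  y <- c(base, base + 0.3, base + 0.6)
  g <- rep(c("a", "b", "c"), each = 50)
  gh <- games_howell(y, g)
  expect_equal(nrow(gh), 3)   # all unordered pairs
  tk <- stats::TukeyHSD(stats::aov(y ~ g))$g
  expect_equal(gh$p_value, unname(tk[, "p adj"]), tolerance = 0.01)
  # by-hand Welch t for one pair
  ya <- y[g == "a"]; yb <- y[g == "b"]
  t_hand <- (mean(ya) - mean(yb)) / sqrt(var(ya) / 50 + var(yb) / 50)
  expect_equal(gh$t[1], t_hand, tolerance = 1e-12)
  # identical groups: t = 0, p = 1
  gh2 <- games_howell(c(ya, ya), rep(c("a", "b"), each = 50))
  expect_equal(gh2$t, 0)
  expect_equal(gh2$p_value, 1)
  expect_error(games_howell(c(1, 1, 2, 3), rep(c("a", "b"), each = 2)),
               "zero-variance")
})

test_that("Games-Howell flags only pairs involving the shifted group", {
  set.seed(77)
  y <- c(rnorm(12), rnorm(12), rnorm(12, 8))
  g <- rep(c("a", "b", "c"), each = 12)
  gh <- games_howell(y, g)
  sig <- gh$p_value < 0.01
  involves_c <- gh$group_i == "c" | gh$group_j == "c"
  expect_identical(sig, involves_c)
})
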