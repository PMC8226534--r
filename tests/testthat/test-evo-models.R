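test_that("Mk likelihood matches exhaustive enumeration and phytools", {
  skip_if_not_installed("phytools")
  tr <- balanced4()
  st <- stats::setNames(c("x", "x", "y", "y"), tr$tip.label)
  fit <- fit_mk(tr, st)
  # exhaustive sum over all ancestral-state combinations
  Q <- fit$Q
  post <- oracle_node_state_posterior(tr, match(st, fit$states), Q)
  # reconstruct total likelihood from the (unnormalized) enumeration
  P <- function(s) {
    ed <- eigen(Q, symmetric = TRUE)
    ed$vectors %*% (exp(ed$values * s) * t(ed$vectors))
  }
  like <- sum(apply(post$combos, 1, function(cc) {
    stn <- c(match(st, fit$states), cc)
    prod(vapply(seq_len(nrow(tr$edge)), function(e)
      P(tr$edge.length[e])[stn[tr$edge[e, 1]], stn[tr$edge[e, 2]]],
      numeric(1))) / 2
  }))
  expect_equal(fit$loglik, log(like), tolerance = 1e-8)
  ref <- phytools::fitMk(tr, st, model = "ER")
  expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-5)
  expect_equal(unname(fit$rates), unname(ref$rates), tolerance = 1e-3)
})

test_that("Mk rate matches a brute-force 1-D likelihood grid", {
  # 2-state ER has the closed-form transition kernel
  # P(same | t) = 1/2 + 1/2 exp(-2 q t); enumerate ancestral states on a
  # fixed 4-tip tree and grid-search q, independent of the pruning code
  tr <- balanced4()
  st_idx <- c(1, 1, 2, 2)    # (x, x, y, y)
  brute_loglik <- function(q) {
    Pm <- function(t, i, j) 0.5 + (if (i == j) 0.5 else -0.5) * exp(-2 * q * t)
    combos <- expand.grid(root = 1:2, n6 = 1:2, n7 = 1:2)
    s <- 0
    for (r in seq_len(nrow(combos))) {
      cc <- combos[r, ]
      stn <- c(st_idx, cc$root, cc$n6, cc$n7)
      s <- s + 0.5 * prod(vapply(seq_len(nrow(tr$edge)), function(e)
        Pm(tr$edge.length[e], stn[tr$edge[e, 1]], stn[tr$edge[e, 2]]),
        numeric(1)))
    }
    log(s)
  }
  grid <- exp(seq(log(0.01), log(5), length.out = 4000))
  best <- grid[which.max(vapply(grid, brute_loglik, numeric(1)))]
  fit <- fit_mk(tr, stats::setNames(c("x", "x", "y", "y"), tr$tip.label))
  expect_equal(unname(fit$rates), best, tolerance = 1e-2)
  # single observed state: zero-rate boundary, flagged
  b <- fit_mk(tr, stats::setNames(rep("p", 4), tr$tip.label))
  expect_true(b$boundary)
  expect_equal(unname(b$rates), 0)
})

test_that("stochastic maps respect branch lengths, tip states, and seeds", {
  tr <- simulate_tree(16, seed = 2)
  truth <- simulate_regimes(tr, 1.2, states = c("u", "v"), seed = 3)
  fit <- fit_mk(tr, truth$tip_states)
  maps <- stochastic_map(fit = fit, n_maps = 8, seed = 5)
  for (m in maps) {
    lens <- vapply(m$segments, function(s) sum(s$length), numeric(1))
    expect_equal(lens, tr$edge.length, tolerance = 1e-10)
    expect_identical(m$tip_states, truth$tip_states)
  }
  m2 <- stochastic_map(fit = fit, n_maps = 8, seed = 5)
  expect_identical(lapply(maps, `[[`, "segments"),
                   lapply(m2, `[[`, "segments"))
  # zero transition rate and uniform tip states: single-regime painting
  one <- fit_mk(tr, stats::setNames(rep("u", 16), tr$tip.label))
  m0 <- stochastic_map(fit = one, n_maps = 2, seed = 1)
  expect_true(all(vapply(m0, function(m)
    all(unlist(lapply(m$segments, `[[`, "regime")) == "u"), logical(1))))
})

test_that("map transition counts agree with matrix-exponential expectations", {
  # fixed 4-tip tree, fixed (not fitted) rates; expected total transitions =
  # sum over edges of E[jumps | endpoints] weighted by the exact endpoint
  # posterior from complete enumeration
  tr <- balanced4()
  states <- c("x", "y")
  Q <- nectarphylo:::mk_Q(0.7, states, "ER")
  st <- stats::setNames(c("x", "x", "y", "y"), tr$tip.label)
  idx <- match(st, states)
  fit <- list(Q = Q, rates = 0.7, states = states, model = "ER",
              tip_states = st, tree = tr, boundary = FALSE, loglik = NA)
  class(fit) <- "mk_fit"
  post <- oracle_node_state_posterior(tr, idx, Q)
  expected <- 0
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    for (r in seq_len(nrow(post$combos))) {
      stn <- c(idx, post$combos[r, ])
      expected <- expected + post$prob[r] *
        oracle_expected_jumps(Q, tr$edge.length[e], stn[par], stn[ch])
    }
  }
  maps <- stochastic_map(tree = tr, tip_states = st, fit = fit,
                         n_maps = 1500, seed = 8)
  counts <- vapply(maps, function(m)
    sum(vapply(m$segments, nrow, integer(1)) - 1L), numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("BM likelihoods: dense matrix equals pruning; BMS reduces to BM1", {
  for (i in 1:10) {
    tr <- simulate_tree(16, seed = 300 + i)
    x <- simulate_trait(tr, "BM", list(sigma2 = 1.5), seed = 400 + i)
    dense <- model_likelihood(tr, x, "BM1", list(sigma2 = 1.5, theta0 = 0.3))
    prune <- oracle_bm_loglik(tr, x, 1.5, 0.3)
    expect_equal(dense, prune, tolerance = 1e-8)
  }
  tr <- simulate_tree(12, seed = 77)
  x <- simulate_trait(tr, "BM", list(sigma2 = 2), seed = 78)
  pt <- simulate_regimes(tr, 1, states = c("r1", "r2"), seed = 79)
  l1 <- model_likelihood(tr, x, "BM1", list(sigma2 = 2, theta0 = 1))
  l2 <- model_likelihood(tr, x, "BMS",
                         list(sigma2 = c(r1 = 2, r2 = 2), theta0 = 1), pt)
  expect_equal(l1, l2, tolerance = 1e-10)
})

test_that("OU likelihood matches the rescaled-tree traversal oracle", {
  for (i in 1:10) {
    tr <- simulate_tree(16, seed = 500 + i)
    pt <- simulate_regimes(tr, 1, states = c("r1", "r2"), seed = 600 + i)
    x <- simulate_trait(tr, "OU",
                        list(sigma2 = 1, alpha = 2, theta = c(r1 = 0, r2 = 4)),
                        painting = pt, seed = 700 + i)
    params <- list(sigma2 = 1.2, alpha = 1.7, theta = c(r1 = 0.5, r2 = 3.5))
    dense <- model_likelihood(tr, x, "OUPG", params, pt)
    W <- nectarphylo:::ou_weight_matrix(pt, params$alpha)
    mu <- stats::setNames(as.numeric(W %*% params$theta[colnames(W)]),
                          rownames(W))
    prune <- oracle_ou_loglik(tr, x, mu, params$sigma2, params$alpha)
    expect_equal(dense, prune, tolerance = 1e-8)
  }
})

test_that("OU1 converges to BM1 as selection vanishes", {
  tr <- simulate_tree(20, seed = 90)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 91)
  lbm <- model_likelihood(tr, x, "BM1", list(sigma2 = 1, theta0 = 0))
  lou <- model_likelihood(tr, x, "OU1",
                          list(sigma2 = 1, alpha = 1e-8, theta = 0))
  expect_lt(abs(lbm - lou), 1e-4)
  # non-ultrametric trees are rejected for OU
  bad <- tr; bad$edge.length[1] <- bad$edge.length[1] + 0.5
  expect_error(model_likelihood(bad, x, "OU1",
                                list(sigma2 = 1, alpha = 1, theta = 0)),
               "ultrametric")
})

test_that("collapsing all regimes reproduces OU1", {
  tr <- simulate_tree(12, seed = 95)
  pt <- simulate_regimes(tr, 1, states = c("r1", "r2"), seed = 96)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 97)
  one <- collapse_regimes(pt, c(r1 = "all", r2 = "all"))
  expect_equal(one$regimes, "all")
  l_pg <- model_likelihood(tr, x, "OUPG",
                           list(sigma2 = 1, alpha = 2, theta = c(all = 1)), one)
  l_ou <- model_likelihood(tr, x, "OU1",
                           list(sigma2 = 1, alpha = 2, theta = 1))
  expect_equal(l_pg, l_ou, tolerance = 1e-10)
})

test_that("AICc arithmetic and model table behave", {
  expect_equal(aicc(-5, 2, 66), 14 + 12 / 63, tolerance = 1e-12)
  expect_error(aicc(-5, 10, 11), "undefined")
  fits <- list(
    tr1 = list(m1 = list(aicc = 10), m2 = list(aicc = 12)),
    tr2 = list(m1 = list(aicc = 7), m2 = list(aicc = 7))
  )
  expect_message(tab <- model_table(fits), "tie")
  expect_equal(tab$best, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(tab$delta_aicc, c(0, 2, 0, 0))
})

test_that("likelihoods are invariant to tip order; AICc increases with k", {
  tr <- simulate_tree(10, seed = 101)
  x <- simulate_trait(tr, "BM", list(sigma2 = 1), seed = 102)
  l1 <- model_likelihood(tr, x, "BM1", list(sigma2 = 1, theta0 = 0))
  l2 <- model_likelihood(tr, rev(x), "BM1", list(sigma2 = 1, theta0 = 0))
  expect_equal(l1, l2, tolerance = 1e-12)
  expect_lt(aicc(-10, 2, 30), aicc(-10, 3, 30))
})

test_that("fitting recovers OU-PG(2) optima and selects the true model", {
  tr <- simulate_tree(48, seed = 110)
  pt <- simulate_regimes(tr, 1.5, states = c("birds", "insects"),
                         root_state = "insects", seed = 111)
  x <- simulate_trait(tr, "OU",
                      list(sigma2 = 1, alpha = 6, theta = c(birds = 8, insects = 0)),
                      painting = pt, seed = 112)
  fpg <- fit_model(tr, x, "OUPG", pt)
  expect_lt(abs(fpg$theta["birds"] - 8), 2)
  expect_lt(abs(fpg$theta["insects"] - 0), 2)
  fbm <- fit_model(tr, x, "BM1")
  fou <- fit_model(tr, x, "OU1")
  expect_lt(fpg$aicc, fbm$aicc)
  expect_lt(fpg$aicc, fou$aicc)
  # averaging over several paintings keeps per-map fits
  fmulti <- fit_model(tr, x, "OUPG", list(pt, pt))
  expect_equal(fmulti$loglik, fpg$loglik, tolerance = 1e-8)
  expect_length(fmulti$per_map, 2)
})
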