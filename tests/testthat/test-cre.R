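test_that("with no subject variance the fit collapses to OLS", {
  dat <- make_cre_data(30, beta0 = 0.3, beta_s = 0.1, tau = 0, sigma = 0.1,
                       seed = 50)
  des <- cre_design(dat$pairs, similarity = dat$sim)
  fit <- fit_cre(dat$y, des)
  ols <- lm(dat$y ~ I(dat$x - mean(dat$x)))
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-3)
  expect_lt(abs(fit$beta["similarity"] - 0.1), 2 * fit$se["similarity"])
})

test_that("REML optimum matches the dense brute-force likelihood", {
  dat <- make_cre_data(5, beta0 = 0.2, beta_s = 0.15, tau = 0.25,
                       sigma = 0.1, seed = 51)
  des <- cre_design(dat$pairs, similarity = dat$sim)
  fit <- fit_cre(dat$y, des)
  ll_hat <- oracle_reml_loglik(dat$y, des$X, des$Z,
                               max(fit$tau2, 0), fit$sigma2)
  # profile agreement at the optimum and no better point nearby
  for (mult in c(0.7, 0.9, 1.1, 1.4)) {
    ll_alt <- oracle_reml_loglik(dat$y, des$X, des$Z,
                                 max(fit$tau2, 1e-8) * mult,
                                 fit$sigma2 * mult)
    expect_lte(ll_alt, ll_hat + 1e-8)
  }
  # the profiled rotated criterion and the dense evaluation describe the
  # same surface: they must rank a grid of variance ratios identically
  pre <- curisc:::.cre_precompute(des)
  yr <- drop(crossprod(pre$Q, dat$y))
  n_p <- length(dat$y) - ncol(des$X)
  grid <- c(0.05, 0.2, 0.5, 1, 2)
  crit <- vapply(grid, function(l) curisc:::.cre_profile(l, yr, pre)$crit,
                 numeric(1))
  dense_ll <- vapply(grid, function(l) {
    pr <- curisc:::.cre_profile(l, yr, pre)
    s2l <- pr$rss / n_p
    oracle_reml_loglik(dat$y, des$X, des$Z, l * s2l, s2l)
  }, numeric(1))
  expect_equal(order(crit), order(-dense_ll))
})

test_that("Monte-Carlo recovery and Wald coverage are calibrated", {
  hits <- 0; est <- numeric(60)
  for (r in 1:60) {
    dat <- make_cre_data(30, beta0 = 0.1, beta_s = 0.2, tau = 0.2,
                         sigma = sqrt(0.02), seed = 600 + r)
    des <- cre_design(dat$pairs, similarity = dat$sim)
    fit <- fit_cre(dat$y, des)
    est[r] <- fit$beta["similarity"]
    ci <- fit$beta["similarity"] + c(-1.96, 1.96) * fit$se["similarity"]
    hits <- hits + (ci[1] <= 0.2 && 0.2 <= ci[2])
  }
  expect_lt(abs(mean(est) - 0.2), 0.02)
  expect_gte(hits / 60, 0.88)
  expect_lte(hits / 60, 1)
})

test_that("estimates are invariant to pair-row permutation", {
  dat <- make_cre_data(12, beta_s = 0.2, seed = 52)
  des <- cre_design(dat$pairs, similarity = dat$sim)
  f1 <- fit_cre(dat$y, des)
  perm <- sample(nrow(dat$pairs))
  pr2 <- dat$pairs[perm, ]
  des2 <- cre_design(pr2, similarity = curisc:::new_similarity(
    pr2, dat$x[perm], "x"))
  f2 <- fit_cre(dat$y[perm], des2)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
  expect_equal(f1$tau2, f2$tau2, tolerance = 1e-6)
})

test_that("rank-deficient designs and short inputs are rejected", {
  pr <- subject_pairs(paste0("s", 1:6))
  flat <- curisc:::new_similarity(pr, rep(0.3, nrow(pr)), "x")
  expect_error(cre_design(pr, similarity = flat), "rank deficient")
  pr3 <- subject_pairs(paste0("s", 1:3))
  expect_error(fit_cre(rnorm(3), cre_design(pr3)), "n_subjects")
})

test_that("voxelwise map fitting equals per-voxel fits and is order-safe", {
  set.seed(53)
  pr <- subject_pairs(paste0("s", 1:10))
  vals <- matrix(rnorm(45 * 8, 0.2, 0.2), 45, 8)
  maps <- make_pairwise_maps(pr, vals, c(2, 2, 2))
  x <- rnorm(45)
  des <- cre_design(pr, similarity = curisc:::new_similarity(pr, x, "x"))
  mf <- fit_cre_map(maps, des)
  for (v in c(1, 5, 8)) {
    single <- fit_cre(vals[, v], des)
    expect_equal(unname(mf$beta[v, ]), unname(single$beta), tolerance = 1e-10)
    expect_equal(mf$tau2[v], single$tau2, tolerance = 1e-10)
  }
  # permuting voxel order permutes the results
  perm <- sample(8)
  mf2 <- fit_cre_map(make_pairwise_maps(pr, vals[, perm], c(2, 2, 2)), des)
  expect_equal(mf2$beta, mf$beta[perm, ], ignore_attr = TRUE)
})

test_that("a planted region stands out from the background", {
  set.seed(54)
  pr <- subject_pairs(paste0("s", 1:16))
  np <- nrow(pr)
  grid <- c(6, 6, 6); nv <- prod(grid)
  scores <- rnorm(16)
  sim_vals <- (scores[pr$i] + scores[pr$j]) / 2
  region <- 1:30
  vals <- matrix(rnorm(np * nv, 0.2, 0.15), np, nv)
  u <- rnorm(16, 0, 0.1)
  vals <- vals + u[pr$i] + u[pr$j]
  vals[, region] <- vals[, region] + 0.3 * sim_vals
  maps <- make_pairwise_maps(pr, vals, grid)
  des <- cre_design(pr, similarity = curisc:::new_similarity(pr, sim_vals, "annak"))
  mf <- fit_cre_map(maps, des)
  expect_gt(mean(mf$stat[region, "similarity"]),
            mean(mf$stat[-region, "similarity"]))
})
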