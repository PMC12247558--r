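test_that("fisher z is the clipped atanh with exact inverse", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), atanh(0.5))
  expect_equal(fisher_z(0.5), 0.54931, tolerance = 1e-5)
  expect_equal(fisher_z(-0.8), -fisher_z(0.8))
  expect_equal(fisher_z(1), atanh(1 - 1e-7))
  r <- seq(-0.99, 0.99, by = 0.11)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-9)
})

test_that("pairwise ISC matches a brute-force correlation loop", {
  set.seed(40)
  arrays <- replicate(5, array(rnorm(4 * 4 * 4 * 50), c(4, 4, 4, 50)),
                      simplify = FALSE)
  names(arrays) <- paste0("s", 1:5)
  isc <- pairwise_isc(arrays)
  expect_equal(nrow(isc$pairs), 10)
  oracle <- oracle_pairwise_isc(arrays)
  expect_equal(tanh(isc$values), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("self-pairs clip and null data follow the Fisher-z sampling law", {
  set.seed(41)
  a <- array(rnorm(3 * 3 * 3 * 594), c(3, 3, 3, 594))
  isc_self <- pairwise_isc(list(s1 = a, s2 = a))
  expect_true(all(isc_self$values == atanh(1 - 1e-7)))
  b <- array(rnorm(3 * 3 * 3 * 594), c(3, 3, 3, 594))
  isc_null <- pairwise_isc(list(s1 = a, s2 = b))
  expect_lt(abs(mean(isc_null$values)), 2 / sqrt(594 - 3))
})

test_that("zero-variance voxels yield 0 with a recorded count", {
  set.seed(42)
  a <- array(rnorm(2 * 2 * 2 * 30), c(2, 2, 2, 30))
  b <- array(rnorm(2 * 2 * 2 * 30), c(2, 2, 2, 30))
  a[1, 1, 1, ] <- 5  # constant time course
  isc <- pairwise_isc(list(s1 = a, s2 = b))
  expect_equal(isc$values[1, 1], 0)
  expect_equal(isc$n_zero_variance, 1L)
})

test_that("pairwise-drop censor policy excludes jointly censored volumes", {
  set.seed(43)
  a <- array(rnorm(2 * 2 * 2 * 40), c(2, 2, 2, 40))
  b <- a + array(rnorm(length(a), 0, 0.3), dim(a))
  b[, , , 31:40] <- -b[, , , 31:40] * 3  # corrupted tail in one subject
  cens <- list(s1 = rep(0L, 40), s2 = c(rep(0L, 30), rep(1L, 10)))
  inc <- pairwise_isc(list(s1 = a, s2 = b), censor_policy = "include",
                      censor = cens)
  drp <- pairwise_isc(list(s1 = a, s2 = b), censor_policy = "pairwise-drop",
                      censor = cens)
  expect_gt(mean(drp$values), mean(inc$values))
  # dropped computation equals plain ISC on the clean volumes
  ref <- pairwise_isc(list(s1 = a[, , , 1:30, drop = FALSE],
                           s2 = b[, , , 1:30, drop = FALSE]))
  expect_equal(drp$values, ref$values, tolerance = 1e-12)
})

test_that("trial similarity handles identical, opposite and flat vectors", {
  v <- rnorm(36)
  expect_warning(
    sim <- trial_similarity(list(a = v, b = -v, c = rep(1, 36))),
    "zero-variance")
  vals <- setNames(sim$values, paste(sim$pairs$subj_i, sim$pairs$subj_j))
  expect_equal(vals[["a b"]], atanh(-(1 - 1e-7)))
  expect_equal(vals[["a c"]], 0)
  sim2 <- trial_similarity(list(a = v, b = v))
  expect_equal(sim2$values, atanh(1 - 1e-7))
})

test_that("shared stimulus-level curiosity raises rating similarity", {
  mean_r <- vapply(c(0.1, 0.8, 2), function(sd_shared) {
    tab <- simulate_behaviour(
      behaviour_sim_config(30, sd_stimulus_curiosity = sd_shared, seed = 44))
    mats <- split(tab$curiosity_centred, tab$subject_id)
    mean(tanh(trial_similarity(mats)$values))
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})

test_that("residualisation is an exact orthogonal projection", {
  set.seed(45)
  pr <- subject_pairs(paste0("s", 1:50))
  target <- curisc:::new_similarity(pr, rnorm(1225), "curiosity")
  covar <- curisc:::new_similarity(pr, rnorm(1225), "memory")
  res <- residualize(target, covar)
  expect_lt(abs(cor(res$values, covar$values)), 1e-10)
  # matches closed-form OLS residuals
  X <- cbind(1, covar$values)
  beta <- solve(t(X) %*% X, t(X) %*% target$values)
  expect_equal(res$values, drop(target$values - X %*% beta),
               tolerance = 1e-12)
  # projection idempotence
  expect_equal(residualize(res, covar)$values, res$values, tolerance = 1e-12)
  # collinear target leaves ~0; constant covariate errors
  expect_lt(max(abs(residualize(covar, covar)$values)), 1e-12)
  flat <- curisc:::new_similarity(pr, rep(1, 1225), "flat")
  expect_error(residualize(target, flat), "constant")
})

test_that("AnnaK similarity is the pair mean of centred scores", {
  s <- c(a = 0.2, b = -0.2, c = 0.2)
  sim <- annak_similarity(s)
  vals <- setNames(sim$values, paste(sim$pairs$subj_i, sim$pairs$subj_j))
  expect_equal(vals[["a b"]], 0)
  expect_equal(vals[["a c"]], 0.2)
  # all-equal scores give a constant matrix; linearity in each argument
  expect_true(all(annak_similarity(c(a = 3, b = 3, c = 3))$values == 3))
  expect_equal(annak_similarity(2 * s)$values, 2 * sim$values)
})

test_that("group coding yields the three pair codes", {
  g <- c(a = "control", b = "control", c = "incentive", d = "incentive")
  gc <- group_code(g)
  vals <- setNames(gc$values, paste(gc$pairs$subj_i, gc$pairs$subj_j))
  expect_equal(vals[["a b"]], 1)    # both control
  expect_equal(vals[["a c"]], 0)    # mixed
  expect_equal(vals[["c d"]], -1)   # both incentive
  expect_true(all(gc$values %in% c(-1, 0, 1)))
})

test_that("grand-mean centring is exact and idempotent", {
  pr <- subject_pairs(paste0("s", 1:3))
  sim <- curisc:::new_similarity(pr, c(1, 2, 3), "x")
  cen <- grand_mean_centre(sim)
  expect_equal(cen$values, c(-1, 0, 1))
  expect_equal(cen$centring, "grand_mean")
  expect_equal(grand_mean_centre(cen)$values, cen$values)
  # interaction column equals the element-wise hand product
  pr4 <- subject_pairs(paste0("s", 1:4))
  gcode <- group_code(setNames(c("control", "control", "incentive",
                                 "incentive"), paste0("s", 1:4)))
  sim4 <- grand_mean_centre(curisc:::new_similarity(pr4, rnorm(6), "x"))
  des <- cre_design(pr4, group = gcode, similarity = sim4,
                    interaction = TRUE)
  expect_equal(unname(des$X[, "group_x_similarity"]),
               gcode$values * sim4$values)
})

test_that("similarity matrices are invariant to subject relabelling", {
  set.seed(46)
  vecs <- replicate(6, rnorm(20), simplify = FALSE)
  names(vecs) <- paste0("s", 1:6)
  sim <- trial_similarity(vecs)
  perm <- c(4, 2, 6, 1, 3, 5)
  sim_p <- trial_similarity(vecs[perm])
  key <- function(s) paste(pmin(s$pairs$subj_i, s$pairs$subj_j),
                           pmax(s$pairs$subj_i, s$pairs$subj_j))
  expect_equal(setNames(sim_p$values, key(sim_p))[key(sim)],
               setNames(sim$values, key(sim)))
})
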