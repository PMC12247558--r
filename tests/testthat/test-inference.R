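test_that("component labelling matches the flood-fill oracle", {
  set.seed(60)
  for (r in 1:5) {
    vol <- array(rbinom(1000, 1, 0.35), c(10, 10, 10))
    lab <- label_components(vol)
    oracle <- oracle_flood_fill(vol)
    # same partition: component memberships agree up to renumbering
    expect_equal(lab != 0, oracle != 0)
    key <- table(lab[lab != 0], oracle[oracle != 0])
    expect_true(all(rowSums(key != 0) == 1))
    expect_true(all(colSums(key != 0) == 1))
  }
})

test_that("face adjacency separates edge- and corner-touching voxels", {
  vol <- array(0, c(4, 4, 4))
  vol[1, 1, 1] <- 1; vol[2, 2, 1] <- 1   # edge contact only
  expect_equal(max(label_components(vol)), 2)
  vol2 <- array(0, c(4, 4, 4))
  vol2[1, 1, 1] <- 1; vol2[2, 2, 2] <- 1  # corner contact only
  expect_equal(max(label_components(vol2)), 2)
  vol3 <- array(0, c(4, 4, 4))
  vol3[1, 1, 1] <- 1; vol3[2, 1, 1] <- 1  # shared face
  expect_equal(max(label_components(vol3)), 1)
})

test_that("cluster-extent thresholding filters and reports clusters", {
  grid <- c(10, 10, 10)
  p <- array(0.5, grid); stat <- array(0.1, grid)
  # one isolated suprathreshold voxel is removed at k = 20
  p1 <- p; s1 <- stat
  p1[5, 5, 5] <- 1e-5; s1[5, 5, 5] <- 5
  out <- cluster_threshold(make_stat_map(p1, s1), k = 20)
  expect_equal(nrow(out$table), 0)
  # a planted 6 x 2 x 2 block survives as exactly one 24-voxel cluster
  p2 <- p; s2 <- stat
  p2[3:8, 2:3, 4:5] <- 1e-5; s2[3:8, 2:3, 4:5] <- 4.2
  out2 <- cluster_threshold(make_stat_map(p2, s2), k = 20)
  expect_equal(nrow(out2$table), 1)
  expect_equal(out2$table$size, 24)
  expect_equal(out2$table$sign, "positive")
  expect_equal(out2$table$peak_stat, 4.2)
  expect_equal(sum(out2$labels != 0), 24)
})

test_that("positive and negative clusters are split and disjoint", {
  grid <- c(8, 8, 8)
  p <- array(0.5, grid); stat <- array(0, grid)
  p[1:3, 1:3, 1:3] <- 1e-4; stat[1:3, 1:3, 1:3] <- 4      # 27 voxels +
  p[6:8, 6:8, 6:8] <- 1e-4; stat[6:8, 6:8, 6:8] <- -4     # 27 voxels -
  out <- cluster_threshold(make_stat_map(p, stat), k = 20)
  expect_setequal(out$table$sign, c("positive", "negative"))
  expect_equal(sort(out$table$size), c(27, 27))
  expect_true(all(out$labels[1:3, 1:3, 1:3] > 0))
  expect_true(all(out$labels[6:8, 6:8, 6:8] < 0))
  empty <- make_stat_map(array(NaN, grid), array(NaN, grid))
  expect_error(cluster_threshold(empty), "mask")
})

test_that("world coordinates come from the affine", {
  grid <- c(6, 6, 6)
  p <- array(0.5, grid); stat <- array(0, grid)
  p[2:6, 3, 3] <- 1e-5; stat[2:6, 3, 3] <- 3
  affine <- rbind(c(2, 0, 0, -10), c(0, 2, 0, -12), c(0, 0, 2, -14),
                  c(0, 0, 0, 1))
  out <- cluster_threshold(make_stat_map(p, stat), k = 2, affine = affine)
  i <- out$table$peak_x
  expect_equal(out$table$world_x, 2 * (i - 1) - 10)
})

test_that("BH selection matches the step-up oracle", {
  set.seed(61)
  for (r in 1:10) {
    pv <- runif(10)^(1 + r / 5)
    ours <- stats::p.adjust(pv, "BH") <= 0.05
    expect_equal(ours, oracle_bh_reject(pv, 0.05))
  }
})

test_that("ROI FDR keeps uniform strong signal and applies extent", {
  grid <- c(8, 8, 8)
  roi <- array(0, grid); roi[2:5, 2:5, 2] <- 1   # 16 voxels
  p <- array(0.5, grid); stat <- array(1, grid)
  p[roi == 1] <- 0.001
  out <- roi_fdr(make_stat_map(p, stat), roi, q = 0.05, k = 5)
  expect_equal(sum(out$table$size), 16)  # all survive
  # 4 surviving voxels in one component are removed at k = 5
  p2 <- array(0.5, grid)
  p2[2:5, 2, 2] <- 1e-6
  out2 <- roi_fdr(make_stat_map(p2, stat), roi, q = 0.05, k = 5)
  expect_equal(nrow(out2$table), 0)
  expect_error(roi_fdr(make_stat_map(p, stat), array(0, grid)), "empty ROI")
})

test_that("ROI FDR is calibrated under a uniform null", {
  set.seed(62)
  grid <- c(10, 10, 5)
  roi <- array(1, grid)   # m = 500
  stat <- array(1, grid)
  any_hit <- vapply(1:200, function(r) {
    p <- array(runif(500), grid)
    out <- roi_fdr(make_stat_map(p, stat), roi, q = 0.05, k = 1)
    nrow(out$table) > 0
  }, logical(1))
  expect_lte(mean(any_hit), 0.10)
})

test_that("permutation null controls the maximum cluster size", {
  set.seed(63)
  pr <- subject_pairs(paste0("s", 1:12))
  np <- nrow(pr); grid <- c(8, 8, 8)
  u <- rnorm(12, 0, 0.15)
  vals <- 0.2 + u[pr$i] + u[pr$j] +
    matrix(rnorm(np * prod(grid), 0, 0.1), np)
  maps <- make_pairwise_maps(pr, vals, grid)
  scores <- rnorm(12)
  sim <- curisc:::new_similarity(pr, (scores[pr$i] + scores[pr$j]) / 2,
                                 "annak")
  out <- permutation_cluster_null(maps, sim, n_perm = 100, p_voxel = 0.01,
                                  seed = 9)
  expect_length(out$max_sizes, 100)
  expect_gte(out$threshold, 0)
  # observed data are drawn from the same null here, so the observed max
  # cluster size should sit inside the support of the permutation null
  des <- cre_design(pr, similarity = sim)
  sm <- stat_map(fit_cre_map(maps, des), "similarity")
  supra <- is.finite(sm$p) & sm$p < 0.01
  obs <- 0
  for (sgn in c(1, -1)) {
    lab <- label_components(supra & sgn * sm$statistic > 0)
    if (any(lab > 0)) obs <- max(obs, max(tabulate(lab[lab > 0])))
  }
  expect_lte(obs, max(out$max_sizes) + 5)
})
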