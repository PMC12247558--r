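# Independent oracles used across the suite. Each is a deliberately
# naive implementation, kept separate from the package's code paths.

# brute-force flood fill for face-adjacency connected components
oracle_flood_fill <- function(vol) {
  d <- dim(vol)
  lab <- array(0L, dim = d)
  nxt <- 0L
  for (start in which(vol != 0)) {
    if (lab[start] != 0) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ci <- arrayInd(v, d)
      for (ax in 1:3) for (dd in c(-1L, 1L)) {
        nb <- ci; nb[ax] <- nb[ax] + dd
        if (nb[ax] < 1 || nb[ax] > d[ax]) next
        lin <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (vol[lin] != 0 && lab[lin] == 0) {
          lab[lin] <- nxt
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# step-up Benjamini-Hochberg by direct definition: reject all p(i) with
# i <= max{ i : p(i) <= i*q/m }
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# dense REML log-likelihood for the pair model with explicit covariance
# V = sigma2 I + tau2 ZZ'
oracle_reml_loglik <- function(y, X, Z, tau2, sigma2) {
  V <- sigma2 * diag(length(y)) + tau2 * tcrossprod(Z)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  drop(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                 t(r) %*% Vi %*% r))
}

# per-voxel per-pair correlation by plain loops
oracle_pairwise_isc <- function(arrays) {
  n <- length(arrays)
  nv <- prod(dim(arrays[[1]])[1:3])
  flat <- lapply(arrays, function(a) matrix(a, nrow = nv))
  out <- list()
  k <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    k <- k + 1
    out[[k]] <- vapply(seq_len(nv), function(v) {
      stats::cor(flat[[i]][v, ], flat[[j]][v, ])
    }, numeric(1))
  }
  do.call(rbind, out)
}

# quick pair-data generator for the crossed model
make_cre_data <- function(N, beta0 = 0.2, beta_s = 0, tau = 0.2,
                          sigma = 0.15, seed = 1) {
  set.seed(seed)
  pr <- subject_pairs(sprintf("s%02d", seq_len(N)))
  u <- rnorm(N, 0, tau)
  x <- rnorm(nrow(pr))
  y <- beta0 + beta_s * x + u[pr$i] + u[pr$j] + rnorm(nrow(pr), 0, sigma)
  list(pairs = pr, x = x, y = y,
       sim = curisc:::new_similarity(pr, x, "x"))
}

make_pairwise_maps <- function(pairs, values, grid) {
  structure(list(pairs = pairs, values = values, mask = NULL,
                 voxel_index = seq_len(prod(grid)), grid = grid,
                 n_timepoints = NA_integer_, n_zero_variance = 0L),
            class = "pairwise_maps")
}

make_stat_map <- function(p, statistic, estimate = statistic) {
  structure(list(estimate = estimate, statistic = statistic, p = p,
                 grid = dim(p), voxel_index = which(is.finite(p)),
                 effect = "test"),
            class = "voxel_stat_map")
}
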