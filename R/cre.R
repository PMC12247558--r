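#' Build a pair-level fixed-effects design for the crossed model
#'
#' Assembles the fixed-effect design matrix used to predict pairwise
#' Fisher-z ISC values: an intercept, optionally the pairwise group
#' deviation code G, optionally a behavioural similarity S (grand-mean
#' centred here unless already centred) and optionally their interaction
#' G x S, together with the pair-to-subject incidence matrix Z needed for
#' the crossed random intercepts.
#'
#' @param pairs pair index data.frame from [subject_pairs()].
#' @param group optional \code{similarity_matrix} of kind
#'   \code{"group_code"}.
#' @param similarity optional behavioural \code{similarity_matrix}.
#' @param interaction include the G x S column (needs both terms).
#' @return list of class \code{cre_design}: \code{X} (pairs x p),
#'   \code{Z} (pairs x subjects incidence), \code{pairs},
#'   \code{n_subjects}.
#' @export
cre_design <- function(pairs, group = NULL, similarity = NULL,
                       interaction = !is.null(group) && !is.null(similarity)) {
  n_pairs <- nrow(pairs)
  subjects <- sort(unique(c(pairs$subj_i, pairs$subj_j)))
  N <- length(subjects)
  stopifnot(n_pairs == N * (N - 1) / 2)
  X <- cbind(intercept = rep(1, n_pairs))
  if (!is.null(group)) {
    stopifnot(length(group$values) == n_pairs)
    X <- cbind(X, group = group$values)
  }
  if (!is.null(similarity)) {
    stopifnot(length(similarity$values) == n_pairs)
    s <- similarity$values
    if (!identical(similarity$centring, "grand_mean")) s <- s - mean(s)
    X <- cbind(X, similarity = s)
  }
  if (interaction) {
    if (is.null(group) || is.null(similarity)) {
      stop("interaction needs both group and similarity", call. = FALSE)
    }
    X <- cbind(X, group_x_similarity = X[, "group"] * X[, "similarity"])
  }
  if (qr(X)$rank < ncol(X)) stop("fixed design is rank deficient", call. = FALSE)
  Z <- matrix(0, n_pairs, N, dimnames = list(NULL, subjects))
  Z[cbind(seq_len(n_pairs), match(pairs$subj_i, subjects))] <- 1
  Z[cbind(seq_len(n_pairs), match(pairs$subj_j, subjects))] <- 1
  structure(list(X = X, Z = Z, pairs = pairs, n_subjects = N),
            class = "cre_design")
}

# Precompute the spectral pieces shared by every response on one design:
# eigendecomposition of K = ZZ' and the rotated fixed design.
.cre_precompute <- function(design) {
  K <- tcrossprod(design$Z)
  eg <- eigen(K, symmetric = TRUE)
  list(Q = eg$vectors, d = pmax(eg$values, 0),
       Xr = crossprod(eg$vectors, design$X), p = ncol(design$X))
}

# Profiled -2 REML criterion at variance ratio lambda = tau2/sigma2, on
# the rotated problem. Returns the criterion and the GLS pieces.
.cre_profile <- function(lambda, yr, pre) {
  w <- 1 / (1 + lambda * pre$d)
  Xw <- pre$Xr * w
  XtWX <- crossprod(pre$Xr, Xw)
  XtWy <- crossprod(Xw, yr)
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  resid <- yr - pre$Xr %*% beta
  rss <- sum(w * resid^2)
  n <- length(yr)
  crit <- (n - pre$p) * log(rss) + sum(log1p(lambda * pre$d)) +
    2 * sum(log(diag(ch)))
  list(crit = crit, beta = drop(beta), rss = rss, XtWX = XtWX)
}

# Satterthwaite degrees of freedom for each fixed effect at the REML
# optimum. theta = (sigma2, tau2); in the rotated basis V = diag(v),
# v_i = sigma2 + tau2 * d_i. For effect c with sampling variance
# f_c = [ (X'V^-1 X)^-1 ]_cc, df_c = 2 f_c^2 / (g_c' I^-1 g_c) with g_c
# the gradient of f_c in theta and I the REML Fisher information.
.cre_satterthwaite_df <- function(pre, sigma2, tau2) {
  v <- sigma2 + tau2 * pre$d
  n <- length(v)
  Xr <- pre$Xr
  A <- crossprod(Xr, Xr / v)
  C <- chol2inv(chol(A))
  # gradient of C's diagonal: dC/dtheta_a = C (X' diag(b_a/v^2) X) C
  grad_diag <- function(b) {
    G <- C %*% crossprod(Xr, Xr * (b / v^2)) %*% C
    diag(G)
  }
  g1 <- grad_diag(rep(1, n))       # d/d sigma2
  g2 <- grad_diag(pre$d)           # d/d tau2
  # REML information: I_ab = 0.5 tr(P B_a P B_b), B_1 = I, B_2 = diag(d)
  # P = diag(1/v) - diag(1/v) Xr C Xr' diag(1/v)
  H <- (Xr / v) %*% tcrossprod(C, Xr / v)   # low-rank part of P
  P <- -H
  diag(P) <- diag(P) + 1 / v
  tr2 <- function(ba, bb) sum((P * rep(ba, each = n)) * t(P * rep(bb, each = n)))
  info <- 0.5 * matrix(c(tr2(rep(1, n), rep(1, n)),
                         tr2(rep(1, n), pre$d),
                         tr2(pre$d, rep(1, n)),
                         tr2(pre$d, pre$d)), 2, 2)
  iinv <- tryCatch(solve(info), error = function(e) NULL)
  fc <- diag(C)
  df <- vapply(seq_along(fc), function(c0) {
    if (is.null(iinv)) return(n - pre$p)
    g <- c(g1[c0], g2[c0])
    denom <- drop(t(g) %*% iinv %*% g)
    if (denom <= 0) return(n - pre$p)
    2 * fc[c0]^2 / denom
  }, numeric(1))
  pmin(pmax(df, 1), n - pre$p)
}

.cre_fit_one <- function(yr, pre, lambda_interval = c(-15, 10),
                         df_method = "satterthwaite") {
  obj <- function(t) .cre_profile(exp(t), yr, pre)$crit
  opt <- stats::optimize(obj, interval = lambda_interval)
  lambda <- exp(opt$minimum)
  at0 <- .cre_profile(0, yr, pre)
  converged <- TRUE
  if (at0$crit <= opt$objective + 1e-8 || lambda < 1e-8) {
    lambda <- 0
    sol <- at0
  } else {
    sol <- .cre_profile(lambda, yr, pre)
    # boundary of the search interval indicates a failed profile
    if (abs(opt$minimum - lambda_interval[2]) < 1e-6) converged <- FALSE
  }
  n <- length(yr)
  sigma2 <- sol$rss / (n - pre$p)
  vb <- sigma2 * chol2inv(chol(sol$XtWX))
  se <- sqrt(diag(vb))
  stat <- sol$beta / se
  if (df_method == "satterthwaite") {
    df <- .cre_satterthwaite_df(pre, sigma2, lambda * sigma2)
    p <- 2 * stats::pt(-abs(stat), df)
  } else {
    df <- rep(Inf, pre$p)
    p <- 2 * stats::pnorm(-abs(stat))
  }
  list(beta = sol$beta, se = se, stat = stat, p = p, df = df,
       tau2 = lambda * sigma2, sigma2 = sigma2,
       reml_crit = if (lambda == 0) at0$crit else sol$crit,
       converged = converged)
}

#' Fit the pair-level linear mixed model with crossed random intercepts
#'
#' Fits \deqn{z_{ij} = x_{ij}^\top\beta + u_i + u_j + e_{ij}}
#' with \eqn{u \sim iid\,N(0, \tau^2)} over subjects (one shared variance
#' for both members of every pair) and \eqn{e \sim iid\,N(0, \sigma^2)},
#' by restricted maximum likelihood. The variance ratio
#' \eqn{\lambda = \tau^2/\sigma^2} is profiled on a log scale over the
#' spectrum of \eqn{ZZ^\top} (computed once per design), with the
#' boundary \eqn{\tau^2 = 0} reported as such, never as an error.
#'
#' Inference on the Wald statistic \eqn{\beta/se} uses, by default, a t
#' reference with Satterthwaite-approximated degrees of freedom: a
#' subject-structured regressor (a group code, or a behavioural
#' similarity built from N subject scores) carries far fewer effective
#' degrees of freedom than the \eqn{N(N-1)/2} pair rows suggest, and the
#' plain normal reference is visibly anticonservative at typical sample
#' sizes. \code{df_method = "normal"} restores the large-sample normal
#' reference.
#'
#' @param y numeric response, one Fisher-z value per pair (one voxel).
#' @param design a [cre_design()].
#' @param df_method \code{"satterthwaite"} (default) or \code{"normal"}.
#' @return list of class \code{cre_fit}: \code{beta}, \code{se},
#'   \code{stat}, \code{p}, \code{df} (named per fixed effect),
#'   \code{tau2}, \code{sigma2}, \code{converged}, \code{reml_crit}.
#' @export
fit_cre <- function(y, design,
                    df_method = c("satterthwaite", "normal")) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(design, "cre_design"),
            length(y) == nrow(design$X), design$n_subjects >= 4)
  pre <- .cre_precompute(design)
  fit <- .cre_fit_one(drop(crossprod(pre$Q, y)), pre, df_method = df_method)
  nm <- colnames(design$X)
  for (f in c("beta", "se", "stat", "p", "df")) names(fit[[f]]) <- nm
  structure(fit, class = "cre_fit")
}

#' Voxelwise crossed-random-effects model over a pairwise map set
#'
#' Fits [fit_cre()] independently at every voxel of a pairwise ISC map
#' set, sharing the design's spectral precomputation, and returns
#' per-effect maps of estimates, Wald statistics and two-sided p-values
#' (Satterthwaite t reference by default, as in [fit_cre()]).
#'
#' @param maps a \code{pairwise_maps} object (see [pairwise_isc()]).
#' @param design a [cre_design()] built on the same pair index.
#' @param df_method \code{"satterthwaite"} (default) or \code{"normal"}.
#' @return list of class \code{cre_map_fit}: \code{effects} (names),
#'   \code{beta}, \code{stat}, \code{p}, \code{df} (voxel x effect
#'   matrices), \code{tau2}, \code{sigma2}, \code{converged} (per
#'   voxel), \code{voxel_index}, \code{grid}.
#' @export
fit_cre_map <- function(maps, design,
                        df_method = c("satterthwaite", "normal")) {
  df_method <- match.arg(df_method)
  stopifnot(inherits(maps, "pairwise_maps"), inherits(design, "cre_design"))
  if (nrow(maps$values) != nrow(design$X)) {
    stop("pair count mismatch between maps and design", call. = FALSE)
  }
  pre <- .cre_precompute(design)
  Yr <- crossprod(pre$Q, maps$values)   # rotated responses, pairs x voxels
  nv <- ncol(Yr)
  p <- ncol(design$X)
  beta <- stat <- pmat <- dfmat <-
    matrix(NA_real_, nv, p, dimnames = list(NULL, colnames(design$X)))
  tau2 <- sigma2 <- numeric(nv)
  converged <- logical(nv)
  for (v in seq_len(nv)) {
    f <- .cre_fit_one(Yr[, v], pre, df_method = df_method)
    beta[v, ] <- f$beta; stat[v, ] <- f$stat; pmat[v, ] <- f$p
    dfmat[v, ] <- f$df
    tau2[v] <- f$tau2; sigma2[v] <- f$sigma2; converged[v] <- f$converged
  }
  structure(list(effects = colnames(design$X), beta = beta, stat = stat,
                 p = pmat, df = dfmat, tau2 = tau2, sigma2 = sigma2,
                 converged = converged, voxel_index = maps$voxel_index,
                 grid = maps$grid),
            class = "cre_map_fit")
}

#' Extract one effect of a voxelwise fit as a statistic map
#'
#' @param fit a \code{cre_map_fit}.
#' @param effect effect name (one of \code{fit$effects}).
#' @return list of class \code{voxel_stat_map}: 3D arrays
#'   \code{estimate}, \code{statistic}, \code{p} (NaN outside the mask),
#'   \code{grid}, \code{voxel_index}, \code{effect}.
#' @export
stat_map <- function(fit, effect) {
  stopifnot(inherits(fit, "cre_map_fit"), effect %in% fit$effects)
  mk <- function(x) {
    arr <- array(NaN, dim = fit$grid)
    arr[fit$voxel_index] <- x
    arr
  }
  structure(list(estimate = mk(fit$beta[, effect]),
                 statistic = mk(fit$stat[, effect]),
                 p = mk(fit$p[, effect]),
                 grid = fit$grid, voxel_index = fit$voxel_index,
                 effect = effect),
            class = "voxel_stat_map")
}
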