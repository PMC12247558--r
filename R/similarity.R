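#' Unordered subject pairs
#'
#' @param subjects character vector of subject ids.
#' @return data.frame \code{i}, \code{j} (indices, i < j), \code{subj_i},
#'   \code{subj_j}; one row per unordered pair.
#' @export
subject_pairs <- function(subjects) {
  n <- length(subjects)
  stopifnot(n >= 2)
  pr <- utils::combn(n, 2)
  data.frame(i = pr[1, ], j = pr[2, ],
             subj_i = subjects[pr[1, ]], subj_j = subjects[pr[2, ]])
}

#' Fisher z-transformation and its inverse
#'
#' \code{fisher_z} clips r to \eqn{\pm(1 - 10^{-7})} before atanh so the
#' transform stays finite at perfect correlation; \code{fisher_z_inv} is
#' tanh.
#'
#' @param r correlation(s) in \eqn{[-1, 1]}.
#' @param z Fisher-z value(s).
#' @return numeric vector.
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) tanh(z)

#' Pairwise voxelwise intersubject correlation maps
#'
#' Correlates, voxel by voxel, the concatenated time course of every
#' unordered subject pair over the retained volumes, then Fisher
#' z-transforms. Zero-variance voxels inside the mask yield 0 (with a
#' recorded count), never NaN.
#'
#' @param concatenated named list of per-subject 4D arrays (equal
#'   dimensions), e.g. from [apply_plan()].
#' @param mask 3D 0/1 array; \code{NULL} keeps every voxel.
#' @param censor_policy \code{"include"} uses all retained volumes as
#'   stored; \code{"pairwise-drop"} drops, per pair, any volume censored
#'   in either subject (requires \code{censor}).
#' @param censor optional per-subject 0/1 vectors aligned with the
#'   concatenated time axis (e.g. \code{plan$censor}).
#' @return list of class \code{pairwise_maps}: \code{pairs} (from
#'   [subject_pairs()]), \code{values} (pairs x masked-voxels matrix of
#'   Fisher z), \code{mask}, \code{voxel_index} (linear indices into the
#'   grid), \code{n_timepoints}, \code{n_zero_variance}.
#' @export
pairwise_isc <- function(concatenated, mask = NULL,
                         censor_policy = c("include", "pairwise-drop"),
                         censor = NULL) {
  censor_policy <- match.arg(censor_policy)
  stopifnot(length(concatenated) >= 2)
  dims <- lapply(concatenated, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("concatenated series differ in dimensions", call. = FALSE)
  }
  grid <- dims[[1]][1:3]; Tn <- dims[[1]][4]
  vox <- if (is.null(mask)) seq_len(prod(grid)) else which(as.logical(mask))
  mats <- lapply(concatenated, function(d) {
    matrix(d, ncol = Tn)[vox, , drop = FALSE]
  })
  subjects <- names(concatenated) %||% as.character(seq_along(concatenated))
  pairs <- subject_pairs(subjects)
  n_zero <- 0L
  vals <- matrix(NA_real_, nrow(pairs), length(vox))
  for (k in seq_len(nrow(pairs))) {
    a <- mats[[pairs$i[k]]]; b <- mats[[pairs$j[k]]]
    if (censor_policy == "pairwise-drop" && !is.null(censor)) {
      keep <- censor[[pairs$i[k]]] == 0 & censor[[pairs$j[k]]] == 0
      a <- a[, keep, drop = FALSE]; b <- b[, keep, drop = FALSE]
    }
    ac <- a - rowMeans(a); bc <- b - rowMeans(b)
    num <- rowSums(ac * bc)
    den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
    r <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
    n_zero <- n_zero + sum(den == 0)
    vals[k, ] <- fisher_z(pmin(pmax(r, -1), 1))
  }
  structure(list(pairs = pairs, values = vals,
                 mask = mask, voxel_index = vox, grid = grid,
                 n_timepoints = Tn, n_zero_variance = n_zero),
            class = "pairwise_maps")
}

#' Behavioural trial-vector similarity between subjects
#'
#' Correlates, for every unordered subject pair, the per-subject
#' trial-ordered values (e.g. subject-wise centred curiosity ratings or
#' dummy-coded high-confidence encoding) aligned to the canonical
#' stimulus order, and Fisher z-transforms. A zero-variance vector (a
#' subject who remembered everything, say) yields pair similarity 0 with
#' a warning rather than dropping the pair.
#'
#' @param vectors named list (or matrix with subjects in columns) of
#'   equal-length numeric vectors in canonical stimulus order.
#' @param kind label stored on the result (e.g. \code{"curiosity"},
#'   \code{"memory"}).
#' @return a \code{similarity_matrix}: \code{pairs}, \code{values}
#'   (Fisher z per pair), \code{kind}, \code{centring = "none"}.
#' @export
trial_similarity <- function(vectors, kind = "curiosity") {
  if (is.matrix(vectors)) {
    vectors <- stats::setNames(asplit(vectors, 2), colnames(vectors))
  }
  lens <- vapply(vectors, length, integer(1))
  stopifnot(length(unique(lens)) == 1)
  subjects <- names(vectors) %||% as.character(seq_along(vectors))
  pairs <- subject_pairs(subjects)
  sds <- vapply(vectors, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance trial vector(s): ",
            paste(subjects[sds == 0], collapse = ", "),
            "; affected pairs set to 0", call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (sds[i] == 0 || sds[j] == 0) return(0)
    fisher_z(stats::cor(vectors[[i]], vectors[[j]]))
  }, numeric(1))
  new_similarity(pairs, vals, kind, centring = "none")
}

new_similarity <- function(pairs, values, kind, centring = "none") {
  structure(list(pairs = pairs, values = values, kind = kind,
                 centring = centring), class = "similarity_matrix")
}

#' Residualise one similarity matrix on another
#'
#' Regresses the target pair values on the covariate pair values (with
#' intercept, ordinary least squares over all pairs) and returns the
#' residuals, isolating the target's unique variance. The residuals are
#' exactly orthogonal to the covariate.
#'
#' @param target,covariate \code{similarity_matrix} objects on the same
#'   pair index.
#' @return a \code{similarity_matrix} with kind
#'   \code{"<target>_unique"}.
#' @export
residualize <- function(target, covariate) {
  stopifnot(inherits(target, "similarity_matrix"),
            inherits(covariate, "similarity_matrix"),
            length(target$values) == length(covariate$values))
  if (stats::sd(covariate$values) == 0) {
    stop("constant covariate: nothing to remove", call. = FALSE)
  }
  res <- stats::residuals(stats::lm(target$values ~ covariate$values))
  new_similarity(target$pairs, unname(res),
                 paste0(target$kind, "_unique"), centring = "none")
}

#' Anna-Karenina pair similarity from per-subject scores
#'
#' The pair value is the mean of the two subjects' scores, reflecting
#' absolute position on the scale: a positive brain-behaviour slope means
#' high scorers are alike (and low scorers heterogeneous), a negative
#' slope the reverse.
#'
#' @param scores named per-subject numeric vector (typically the
#'   mean-centred CMLE scores from [extract_cmle()]).
#' @return a \code{similarity_matrix} with kind \code{"annak_cmle"}.
#' @export
annak_similarity <- function(scores) {
  subjects <- names(scores) %||% as.character(seq_along(scores))
  pairs <- subject_pairs(subjects)
  vals <- (scores[pairs$i] + scores[pairs$j]) / 2
  new_similarity(pairs, unname(vals), "annak_cmle", centring = "none")
}

#' Pairwise group deviation code
#'
#' Subjects are deviation-coded +0.5 (control) / -0.5 (incentive); the
#' pair value is the sum of the two codes: 1 for two control subjects, 0
#' for a mixed pair, -1 for two incentive subjects.
#'
#' @param assignments named character vector of \code{"control"} /
#'   \code{"incentive"} per subject.
#' @return a \code{similarity_matrix} with kind \code{"group_code"}.
#' @export
group_code <- function(assignments) {
  stopifnot(all(assignments %in% c("control", "incentive")))
  code <- ifelse(assignments == "control", 0.5, -0.5)
  subjects <- names(assignments) %||% as.character(seq_along(assignments))
  pairs <- subject_pairs(subjects)
  new_similarity(pairs, unname(code[pairs$i] + code[pairs$j]),
                 "group_code", centring = "none")
}

#' Grand-mean centre a similarity matrix
#'
#' Subtracts the mean over all pairs; applied to behavioural similarity
#' before forming its interaction with the group code so the group main
#' effect stays interpretable.
#'
#' @param sim a \code{similarity_matrix}.
#' @return the centred \code{similarity_matrix}
#'   (\code{centring = "grand_mean"}).
#' @export
grand_mean_centre <- function(sim) {
  stopifnot(inherits(sim, "similarity_matrix"))
  sim$values <- sim$values - mean(sim$values)
  sim$centring <- "grand_mean"
  sim
}
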