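#' Build a concatenation plan for volume selection and reordering
#'
#' For every subject, finds the trick-window volumes (volumes of no
#' interest — mock, fixation, rating — are discarded), shifts each
#' window forward by \code{lag_tr} volumes so the delayed hemodynamic
#' response is captured, and orders the windows by the canonical stimulus
#' order so concatenated series are aligned stimulus-by-stimulus across
#' subjects regardless of each subject's pseudo-randomised presentation
#' order.
#'
#' @param labels named list of per-subject volume-label data.frames
#'   (\code{stimulus_id}, \code{volume_class}, \code{censor}).
#' @param canonical_order character vector of stimulus ids defining the
#'   concatenated order; defaults to the sorted ids of the first subject.
#' @param lag_tr non-negative integer lag in volumes.
#' @return a \code{concat_plan}: \code{canonical_order}, \code{lag_tr},
#'   \code{retained_index} (per-subject integer vectors, equal length),
#'   \code{censor} (per-subject 0/1 vectors for the retained volumes),
#'   \code{n_retained}.
#' @export
build_plan <- function(labels, canonical_order = NULL, lag_tr = 0L) {
  stopifnot(is.list(labels), length(labels) >= 1, lag_tr >= 0)
  lag_tr <- as.integer(lag_tr)
  if (is.null(canonical_order)) {
    canonical_order <- sort(unique(stats::na.omit(labels[[1]]$stimulus_id)))
  }
  per_subj <- lapply(labels, function(lab) {
    trick <- which(lab$volume_class == "trick")
    split(trick, lab$stimulus_id[trick])
  })
  counts <- lapply(per_subj, function(x) vapply(x, length, integer(1)))
  ref <- counts[[1]][canonical_order]
  if (any(is.na(ref))) {
    stop("canonical stimulus missing from subject 1: ",
         paste(canonical_order[is.na(ref)], collapse = ", "), call. = FALSE)
  }
  for (i in seq_along(counts)) {
    ci <- counts[[i]][canonical_order]
    bad <- which(is.na(ci) | ci != ref)
    if (length(bad)) {
      stop("per-stimulus trick-volume count mismatch for subject ",
           names(labels)[i] %||% i, " at stimulus ",
           paste(canonical_order[bad], collapse = ", "), call. = FALSE)
    }
  }
  retained <- lapply(seq_along(labels), function(i) {
    unlist(lapply(canonical_order, function(s) per_subj[[i]][[s]] + lag_tr),
           use.names = FALSE)
  })
  censor <- lapply(seq_along(labels), function(i) {
    n_t <- nrow(labels[[i]])
    idx <- retained[[i]]
    ifelse(idx <= n_t, labels[[i]]$censor[pmin(idx, n_t)], 0L)
  })
  names(retained) <- names(censor) <- names(labels)
  structure(list(canonical_order = canonical_order, lag_tr = lag_tr,
                 retained_index = retained, censor = censor,
                 n_retained = length(retained[[1]])),
            class = "concat_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a concatenation plan to one subject's series
#'
#' Copies the planned volumes (no interpolation) in plan order. Errors if
#' the lag pushes any index past the end of the acquisition.
#'
#' @param series a labelled time series (list with 4D \code{data} and
#'   \code{volume_labels}; see [simulate_fmri()]).
#' @param plan a \code{concat_plan}.
#' @param subject_id which subject's index to use; defaults to
#'   \code{series$subject_id}.
#' @return 4D array (x, y, z, plan length).
#' @export
apply_plan <- function(series, plan, subject_id = series$subject_id) {
  stopifnot(inherits(plan, "concat_plan"))
  idx <- plan$retained_index[[subject_id]]
  if (is.null(idx)) stop("subject not in plan: ", subject_id, call. = FALSE)
  n_t <- dim(series$data)[4]
  if (any(idx < 1 | idx > n_t)) {
    stop("plan index out of range for subject ", subject_id,
         " (lag shift past acquisition end?)", call. = FALSE)
  }
  series$data[, , , idx, drop = FALSE]
}

#' Select the hemodynamic lag by intersubject pattern correlation
#'
#' For each candidate lag, concatenates every subject with that lag and
#' computes, at every retained time point, the spatial Pearson
#' correlation of the masked voxel patterns for every unordered subject
#' pair; the mean over time points and pairs is the lag's ISPC score.
#' Returns the arg-max lag together with the full score table.
#'
#' @param series_set named list of labelled time series.
#' @param mask logical/0-1 3D array selecting voxels (must select >= 2).
#' @param candidate_lags integer vector of lags to score.
#' @param canonical_order passed to [build_plan()].
#' @return list with \code{lag_tr} (selected) and \code{scores}
#'   (data.frame \code{lag}, \code{ispc}).
#' @export
select_lag <- function(series_set, mask, candidate_lags = 0:6,
                       canonical_order = NULL) {
  stopifnot(length(series_set) >= 2)
  vmask <- which(as.logical(mask))
  if (length(vmask) < 2) stop("mask selects fewer than 2 voxels", call. = FALSE)
  labels <- lapply(series_set, `[[`, "volume_labels")
  scores <- vapply(candidate_lags, function(L) {
    plan <- build_plan(labels, canonical_order, lag_tr = L)
    mats <- lapply(series_set, function(s) {
      d <- apply_plan(s, plan)
      matrix(d, ncol = dim(d)[4])[vmask, , drop = FALSE]
    })
    # standardise columns (spatial patterns) once per subject
    zs <- lapply(mats, function(m) scale(m))
    pr <- utils::combn(length(zs), 2)
    mean(vapply(seq_len(ncol(pr)), function(k) {
      a <- zs[[pr[1, k]]]; b <- zs[[pr[2, k]]]
      mean(colSums(a * b) / (nrow(a) - 1))
    }, numeric(1)))
  }, numeric(1))
  tab <- data.frame(lag = candidate_lags, ispc = scores)
  list(lag_tr = candidate_lags[which.max(scores)], scores = tab)
}

#' Build a group grey-matter mask by subject-wise majority
#'
#' A voxel enters the group mask iff it is marked in at least
#' \code{threshold} of the subject masks (inclusive, so a voxel present
#' in exactly half the sample is kept at the default 0.5).
#'
#' @param subject_masks list of 3D 0/1 arrays on one grid.
#' @param threshold fraction in (0, 1].
#' @return 3D 0/1 array.
#' @export
group_gm_mask <- function(subject_masks, threshold = 0.5) {
  stopifnot(length(subject_masks) >= 1)
  dims <- lapply(subject_masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("subject masks are on different grids", call. = FALSE)
  }
  mean_mask <- Reduce(`+`, lapply(subject_masks, function(m) (m != 0) + 0)) /
    length(subject_masks)
  (mean_mask >= threshold) + 0
}
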