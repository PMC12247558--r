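#' Label connected components of a binary 3D volume (face adjacency)
#'
#' First-nearest-neighbour clustering: two suprathreshold voxels belong
#' to one component only if they share a face (6-connectivity); edge- or
#' corner-touching voxels are separate components.
#'
#' @param vol 3D logical/0-1 array.
#' @return integer 3D array; 0 background, components numbered from 1 in
#'   decreasing size order.
#' @export
label_components <- function(vol) {
  stopifnot(length(dim(vol)) == 3)
  idx <- which(vol != 0)
  lab <- array(0L, dim = dim(vol))
  if (!length(idx)) return(lab)
  d <- dim(vol)
  coord <- arrayInd(idx, d)
  pos <- integer(prod(d)); pos[idx] <- seq_along(idx)
  edges <- list()
  for (ax in 1:3) {
    nb <- coord
    nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    nb_lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * d[1] +
      (nb[ok, 3] - 1L) * d[1] * d[2]
    hit <- pos[nb_lin] > 0
    edges[[ax]] <- cbind(which(ok)[hit], pos[nb_lin[hit]])
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(em), ncol = 2), directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(seq_along(idx)),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  membership <- comp$membership[as.character(seq_along(idx))]
  # renumber by decreasing size
  sizes <- table(membership)
  rank <- stats::setNames(order(order(-as.integer(sizes))), names(sizes))
  lab[idx] <- as.integer(rank[as.character(membership)])
  lab
}

.cluster_table_one <- function(supra, stat, k, sign_label, affine = NULL) {
  lab <- label_components(supra)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  rows <- lapply(ids, function(cl) {
    vox <- which(lab == cl)
    if (length(vox) < k) return(NULL)
    pk <- vox[which.max(abs(stat[vox]))]
    ci <- arrayInd(pk, dim(stat))
    world <- if (!is.null(affine)) {
      drop(affine %*% c(ci - 1L, 1))[1:3]
    } else c(NA_real_, NA_real_, NA_real_)
    data.frame(size = length(vox), peak_stat = stat[pk],
               peak_x = ci[1], peak_y = ci[2], peak_z = ci[3],
               world_x = world[1], world_y = world[2], world_z = world[3],
               sign = sign_label)
  })
  keep_ids <- ids[!vapply(rows, is.null, logical(1))]
  tab <- do.call(rbind, rows)
  lab[!(lab %in% keep_ids)] <- 0L
  list(table = tab, labels = lab)
}

#' Whole-brain cluster-extent thresholding
#'
#' Thresholds a voxelwise p map at \code{p_voxel}, labels suprathreshold
#' voxels by face-adjacency connected components separately for positive
#' and negative statistics, and retains components of at least \code{k}
#' voxels (inclusive).
#'
#' @param map a \code{voxel_stat_map} (see [stat_map()]).
#' @param p_voxel voxelwise threshold (default 0.001; p strictly below
#'   passes).
#' @param k minimum cluster extent in voxels (default 20).
#' @param affine optional 4x4 voxel-to-world affine for peak coordinates
#'   (0-based voxel indices).
#' @return list: \code{table} (cluster data.frame with \code{cluster_id},
#'   \code{size}, \code{peak_stat}, peak voxel and world coordinates,
#'   \code{sign}), \code{labels} (integer 3D array; positive clusters
#'   numbered, negative clusters numbered with negative sign).
#' @export
cluster_threshold <- function(map, p_voxel = 0.001, k = 20, affine = NULL) {
  stopifnot(inherits(map, "voxel_stat_map"))
  inmask <- is.finite(map$p)
  if (!any(inmask)) stop("empty analysis mask", call. = FALSE)
  supra <- inmask & map$p < p_voxel
  pos <- .cluster_table_one(supra & map$statistic > 0, map$statistic, k,
                            "positive", affine)
  neg <- .cluster_table_one(supra & map$statistic < 0, map$statistic, k,
                            "negative", affine)
  labels <- pos$labels - neg$labels
  tab <- rbind(pos$table, neg$table)
  if (!is.null(tab) && nrow(tab)) {
    tab <- tab[order(-tab$size), , drop = FALSE]
    tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster_id = integer(), size = integer(),
                      peak_stat = numeric(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer(),
                      world_x = numeric(), world_y = numeric(),
                      world_z = numeric(), sign = character())
  }
  list(table = tab, labels = labels)
}

#' ROI inference: Benjamini-Hochberg FDR plus a minimum cluster extent
#'
#' Applies the BH step-up procedure to the p-values of the voxels inside
#' the region of interest at level \code{q}, then labels surviving
#' voxels by face adjacency and keeps components of at least \code{k}
#' voxels.
#'
#' @param map a \code{voxel_stat_map}.
#' @param roi_mask 3D 0/1 array; must lie inside the analysis mask.
#' @param q FDR level (default 0.05).
#' @param k minimum cluster extent (default 5).
#' @param affine optional voxel-to-world affine.
#' @return as [cluster_threshold()].
#' @export
roi_fdr <- function(map, roi_mask, q = 0.05, k = 5, affine = NULL) {
  stopifnot(inherits(map, "voxel_stat_map"))
  roi <- which(as.logical(roi_mask))
  if (!length(roi)) stop("empty ROI", call. = FALSE)
  pv <- map$p[roi]
  if (any(!is.finite(pv))) {
    stop("ROI extends outside the analysis mask", call. = FALSE)
  }
  padj <- stats::p.adjust(pv, method = "BH")
  surv <- array(FALSE, dim = dim(map$p))
  surv[roi[padj <= q]] <- TRUE
  pos <- .cluster_table_one(surv & map$statistic > 0, map$statistic, k,
                            "positive", affine)
  neg <- .cluster_table_one(surv & map$statistic < 0, map$statistic, k,
                            "negative", affine)
  tab <- rbind(pos$table, neg$table)
  if (!is.null(tab) && nrow(tab)) {
    tab <- tab[order(-tab$size), , drop = FALSE]
    tab <- cbind(cluster_id = seq_len(nrow(tab)), tab)
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(cluster_id = integer(), size = integer(),
                      peak_stat = numeric(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer(),
                      world_x = numeric(), world_y = numeric(),
                      world_z = numeric(), sign = character())
  }
  list(table = tab, labels = pos$labels - neg$labels)
}

#' Permutation null distribution of the maximum cluster size
#'
#' Estimates a cluster-extent threshold by permuting the subject-level
#' behavioural scores (not the raw pair rows, which are not exchangeable
#' under the crossed dependence), rebuilding the pairwise similarity from
#' the permuted scores, refitting the voxelwise crossed model and
#' recording the maximum suprathreshold cluster size of the similarity
#' effect in each permutation.
#'
#' @param maps a \code{pairwise_maps} object.
#' @param similarity behavioural \code{similarity_matrix} whose subject
#'   labels are permuted.
#' @param group optional \code{similarity_matrix} of group codes (held
#'   fixed).
#' @param effect which effect's map to cluster (default
#'   \code{"similarity"}).
#' @param n_perm number of permutations (>= 100).
#' @param p_voxel voxelwise threshold applied before clustering.
#' @param seed integer seed for the permutation stream.
#' @return list: \code{threshold} (95th percentile of max cluster size),
#'   \code{max_sizes} (per permutation).
#' @export
permutation_cluster_null <- function(maps, similarity, group = NULL,
                                     effect = "similarity", n_perm = 100,
                                     p_voxel = 0.001, seed = 1L) {
  stopifnot(n_perm >= 100)
  set.seed(seed)
  pairs <- maps$pairs
  N <- length(unique(c(pairs$subj_i, pairs$subj_j)))
  # pair lookup by subject indices for fast relabelling
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  val_of <- stats::setNames(similarity$values, key(pairs$i, pairs$j))
  max_sizes <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    perm <- sample.int(N)
    sim_b <- similarity
    sim_b$values <- unname(val_of[key(perm[pairs$i], perm[pairs$j])])
    des <- cre_design(pairs, group = group, similarity = sim_b,
                      interaction = !is.null(group))
    fit <- fit_cre_map(maps, des)
    sm <- stat_map(fit, effect)
    supra <- is.finite(sm$p) & sm$p < p_voxel
    mx <- 0L
    for (sgn in c(1, -1)) {
      lab <- label_components(supra & sgn * sm$statistic > 0)
      if (any(lab > 0)) mx <- max(mx, max(tabulate(lab[lab > 0])))
    }
    max_sizes[b] <- mx
  }
  list(threshold = unname(stats::quantile(max_sizes, 0.95, type = 1)),
       max_sizes = max_sizes)
}
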