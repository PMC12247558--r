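#' Configuration for the synthetic naturalistic-fMRI generator
#'
#' The generator decomposes every voxel's time course into a
#' stimulus-locked signal shared by all subjects, a subject-idiosyncratic
#' component, and white measurement noise. Under this decomposition the
#' expected pairwise intersubject correlation at any voxel is
#' \deqn{\rho = \sigma^2_{shared} / (\sigma^2_{shared} +
#'   \sigma^2_{idio} + \sigma^2_{noise}).}
#' Each trial consists of a mock prefix, the trick (stimulus) window, a
#' fixation gap and a rating window; only trick volumes are of interest
#' downstream. The stimulus-locked component is delayed by
#' \code{true_lag_tr} whole volumes, emulating the hemodynamic lag.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_stimuli number of stimuli.
#' @param volumes_per_stimulus trick-window length in volumes; either a
#'   single count or a per-stimulus vector (stimulus durations vary in
#'   naturalistic designs).
#' @param mock_volumes,fixation_volumes,rating_volumes per-trial counts of
#'   volumes of no interest before/after each trick window.
#' @param voxel_grid integer 3-vector, the spatial grid.
#' @param tr_seconds repetition time in seconds.
#' @param sd_shared,sd_idiosyncratic,sd_noise standard deviations of the
#'   three signal components, all \eqn{\ge 0}.
#' @param true_lag_tr non-negative integer; volumes by which the
#'   stimulus-locked component lags the stimulus.
#' @param annak_scores optional per-subject scalar in \eqn{[0, 1]}
#'   modulating idiosyncratic amplitude (see \code{annak_direction});
#'   default \code{NULL} applies no modulation.
#' @param annak_direction \code{"high_alike"} scales idiosyncratic
#'   amplitude by \code{1 - score} (high scorers carry less idiosyncrasy,
#'   hence resemble everyone); \code{"low_alike"} scales by \code{score}.
#' @param trial_orders optional list of per-subject permutations of
#'   \code{1:n_stimuli}; default draws independent pseudo-random orders.
#' @param seed integer seed.
#' @return an object of class \code{fmri_sim_config}.
#' @export
fmri_sim_config <- function(n_subjects,
                            n_stimuli = 36,
                            volumes_per_stimulus = 16,
                            mock_volumes = 3,
                            fixation_volumes = 2,
                            rating_volumes = 2,
                            voxel_grid = c(12, 12, 12),
                            tr_seconds = 2,
                            sd_shared = 1,
                            sd_idiosyncratic = 0,
                            sd_noise = 1,
                            true_lag_tr = 0,
                            annak_scores = NULL,
                            annak_direction = c("high_alike", "low_alike"),
                            trial_orders = NULL,
                            seed = 1L) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (any(c(sd_shared, sd_idiosyncratic, sd_noise) < 0)) {
    stop("signal SDs must be >= 0", call. = FALSE)
  }
  if (true_lag_tr < 0) stop("true_lag_tr must be >= 0", call. = FALSE)
  stopifnot(length(voxel_grid) == 3)
  vols <- rep_len(as.integer(volumes_per_stimulus), n_stimuli)
  if (any(vols < 1)) stop("volumes_per_stimulus must be >= 1", call. = FALSE)
  annak_direction <- match.arg(annak_direction)
  if (!is.null(annak_scores)) stopifnot(length(annak_scores) == n_subjects)
  if (!is.null(trial_orders)) {
    stopifnot(length(trial_orders) == n_subjects)
    ok <- vapply(trial_orders,
                 function(o) identical(sort(as.integer(o)), seq_len(n_stimuli)),
                 logical(1))
    if (!all(ok)) stop("trial_orders must be permutations of 1:n_stimuli",
                       call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), n_stimuli = as.integer(n_stimuli),
    volumes_per_stimulus = vols,
    mock_volumes = as.integer(mock_volumes),
    fixation_volumes = as.integer(fixation_volumes),
    rating_volumes = as.integer(rating_volumes),
    voxel_grid = as.integer(voxel_grid), tr_seconds = tr_seconds,
    sd_shared = sd_shared, sd_idiosyncratic = sd_idiosyncratic,
    sd_noise = sd_noise, true_lag_tr = as.integer(true_lag_tr),
    annak_scores = annak_scores, annak_direction = annak_direction,
    trial_orders = trial_orders, seed = as.integer(seed)
  ), class = "fmri_sim_config")
}

# Per-trial label block for one stimulus: mock prefix, trick window,
# fixation, rating. Returns a data.frame of volume labels.
.trial_labels <- function(cfg, stim) {
  n_trick <- cfg$volumes_per_stimulus[stim]
  cls <- c(rep("mock", cfg$mock_volumes), rep("trick", n_trick),
           rep("fixation", cfg$fixation_volumes),
           rep("rating", cfg$rating_volumes))
  data.frame(stimulus_id = sprintf("stim-%02d", stim),
             volume_class = cls, censor = 0L)
}

#' Simulate labelled 4D time series for a set of subjects
#'
#' Assembles each subject's acquisition in that subject's presentation
#' order and adds, voxelwise, shared stimulus-locked signal (identical
#' across subjects for the same stimulus and within-trick volume, delayed
#' by \code{true_lag_tr} volumes), an idiosyncratic component (drawn
#' independently per subject, amplitude optionally modulated by the
#' Anna-Karenina scores) and white noise. Shared and idiosyncratic
#' components are active only during trick windows; volumes of no
#' interest contain noise alone.
#'
#' @param cfg an [fmri_sim_config()].
#' @return a list of labelled time series, one per subject; each element
#'   has \code{data} (4D array x,y,z,t), \code{tr_seconds},
#'   \code{volume_labels} (data.frame: \code{stimulus_id},
#'   \code{volume_class}, \code{censor}), \code{subject_id} and
#'   \code{group}.
#' @export
simulate_fmri <- function(cfg) {
  stopifnot(inherits(cfg, "fmri_sim_config"))
  set.seed(cfg$seed)
  N <- cfg$n_subjects; S <- cfg$n_stimuli
  V <- prod(cfg$voxel_grid)
  lag <- cfg$true_lag_tr

  orders <- cfg$trial_orders
  if (is.null(orders)) orders <- replicate(N, sample.int(S), simplify = FALSE)

  # shared stimulus-locked signal: V x (trick volumes) per stimulus
  shared <- lapply(seq_len(S), function(s) {
    matrix(rnorm(V * cfg$volumes_per_stimulus[s], 0, cfg$sd_shared),
           nrow = V)
  })

  idio_scale <- rep(1, N)
  if (!is.null(cfg$annak_scores)) {
    sc <- cfg$annak_scores
    rng <- range(sc)
    norm <- if (diff(rng) > 0) (sc - rng[1]) / diff(rng) else rep(0.5, N)
    idio_scale <- if (cfg$annak_direction == "high_alike") 1 - norm else norm
  }

  group <- rep(c("control", "incentive"), length.out = N)
  out <- vector("list", N)
  for (i in seq_len(N)) {
    labs <- do.call(rbind, lapply(orders[[i]], function(s) .trial_labels(cfg, s)))
    labs$stimulus_id[labs$volume_class %in% c("fixation", "rating")] <- NA
    Tn <- nrow(labs)
    dat <- matrix(rnorm(V * Tn, 0, cfg$sd_noise), nrow = V)
    # place shared + idiosyncratic signal into trick windows, shifted by lag
    pos <- 0L
    for (s in orders[[i]]) {
      n_trick <- cfg$volumes_per_stimulus[s]
      trick_start <- pos + cfg$mock_volumes + 1L
      idx <- trick_start:(trick_start + n_trick - 1L) + lag
      keep <- idx <= Tn
      if (any(keep)) {
        sig <- shared[[s]][, keep, drop = FALSE]
        if (cfg$sd_idiosyncratic > 0) {
          sig <- sig + idio_scale[i] *
            matrix(rnorm(V * sum(keep), 0, cfg$sd_idiosyncratic), nrow = V)
        }
        dat[, idx[keep]] <- dat[, idx[keep], drop = FALSE] + sig
      }
      pos <- pos + cfg$mock_volumes + n_trick + cfg$fixation_volumes +
        cfg$rating_volumes
    }
    out[[i]] <- list(
      data = array(dat, dim = c(cfg$voxel_grid, Tn)),
      tr_seconds = cfg$tr_seconds,
      volume_labels = labs,
      subject_id = sprintf("sub-%03d", i),
      group = group[i]
    )
  }
  names(out) <- vapply(out, `[[`, character(1), "subject_id")
  out
}
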