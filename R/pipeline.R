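#' Run the behavioural arm end to end
#'
#' For every study's trial table: codes memory at the requested cutoffs,
#' fits the logistic mixed model (falling back to the reduced variant
#' when the full fit is singular), pools coefficients across studies by
#' inverse-variance fixed-effect meta-analysis, regresses the pooled
#' curiosity effect on the confidence cutoff, and extracts mean-centred
#' CMLE scores from the first study's full high-confidence fit for the
#' imaging arm.
#'
#' @param studies named list of trial tables (each with
#'   \code{curiosity_centred} already present or computable via
#'   [centre_curiosity()]).
#' @param cutoffs integer vector of confidence cutoffs to sweep.
#' @param measures character; memory measures for the headline table.
#' @param variant model variant to attempt first.
#' @param verbose print stage messages.
#' @return list: \code{fits} (per study x measure), \code{meta}
#'   (Table-2-shaped data.frame over measures x effects),
#'   \code{sweep} (pooled estimates per cutoff x effect),
#'   \code{cutoff_model} (per effect regression on cutoff),
#'   \code{cmle} (per-subject scores), \code{log}.
#' @export
run_behavioural <- function(studies, cutoffs = 0:5,
                            measures = c("recognition", "highconf", "recall"),
                            variant = "full", verbose = FALSE) {
  stopifnot(length(studies) >= 1)
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  studies <- lapply(studies, centre_curiosity)

  fit_one <- function(tab, outcome) {
    f <- fit_glme(tab, outcome, variant = variant)
    if (f$singular && variant == "full") {
      say("singular full fit; refitting reduced")
      f <- fit_glme(tab, outcome, variant = "reduced")
    }
    f
  }
  outcome_for <- function(tab, measure) {
    switch(measure,
           recognition = code_memory(tab, 0, "recognition"),
           highconf = code_memory(tab, 3, "recognition"),
           recall = code_memory(tab, 0, "recall"),
           stop("unknown measure: ", measure))
  }

  fits <- list()
  for (m in measures) {
    fits[[m]] <- lapply(names(studies), function(st) {
      say("fitting ", m, " for study ", st)
      fit_one(studies[[st]], outcome_for(studies[[st]], m))
    })
    names(fits[[m]]) <- names(studies)
  }

  effects <- c("curiosity_centred", "incentive_code", "curiosity_x_incentive")
  pool <- function(fit_list, eff) {
    est <- do.call(rbind, lapply(names(fit_list), function(st) {
      fe <- fit_list[[st]]$fixed_effects
      row <- fe[fe$effect == eff, ]
      data.frame(study_id = st, effect_name = eff, b = row$b, SE = row$SE)
    }))
    fixed_effect_meta(est)
  }
  meta <- do.call(rbind, lapply(measures, function(m) {
    out <- do.call(rbind, lapply(effects, function(e) pool(fits[[m]], e)))
    cbind(measure = m, out)
  }))

  sweep_rows <- list()
  for (cu in cutoffs) {
    cfits <- lapply(names(studies), function(st) {
      fit_one(studies[[st]], code_memory(studies[[st]], cu, "recognition"))
    })
    names(cfits) <- names(studies)
    for (e in effects) {
      pooled <- pool(cfits, e)
      sweep_rows[[length(sweep_rows) + 1L]] <-
        cbind(cutoff = cu, pooled)
    }
  }
  sweep <- do.call(rbind, sweep_rows)
  cutoff_model <- NULL
  if (length(cutoffs) >= 3) {
    cutoff_model <- do.call(rbind, lapply(effects, function(e) {
      cbind(effect_name = e,
            cutoff_regression(sweep[sweep$effect_name == e, ]))
    }))
  } else {
    say("fewer than 3 cutoffs: cutoff regression skipped")
  }

  # CMLE always comes from a full high-confidence fit of the first
  # (imaging) study, even when the headline fit fell back to the reduced
  # variant: mean-centring makes the scores insensitive to that choice,
  # and a collapsed slope variance simply yields all-zero scores.
  hc_full <- fit_glme(studies[[1]], outcome_for(studies[[1]], "highconf"),
                      variant = "full")
  if (hc_full$singular) say("full high-confidence CMLE fit is singular")
  cmle <- extract_cmle(hc_full)
  list(fits = fits, meta = meta, sweep = sweep,
       cutoff_model = cutoff_model, cmle = cmle, log = log)
}

#' Run the imaging arm end to end
#'
#' Lag selection (or a fixed lag), concatenation, pairwise ISC, the
#' group-effect model, and the three IS-RSA models (unique curiosity,
#' unique memory, Anna-Karenina CMLE), each with the group interaction,
#' followed by whole-brain cluster-extent and ROI FDR inference on the
#' similarity effect.
#'
#' @param series_set named list of labelled time series.
#' @param mask 3D analysis mask.
#' @param behaviour list with per-subject trial-ordered vectors
#'   \code{curiosity} and \code{memory} (named lists/matrices aligned to
#'   the canonical stimulus order) and per-subject \code{cmle} scores.
#' @param groups named character vector \code{"control"}/
#'   \code{"incentive"} per subject.
#' @param lag_tr fixed lag, or \code{NULL} to select by ISPC over
#'   \code{candidate_lags}.
#' @param candidate_lags lags scored when \code{lag_tr} is NULL.
#' @param censor_policy passed to [pairwise_isc()].
#' @param p_voxel,k_cluster whole-brain thresholds.
#' @param q_fdr,k_roi ROI thresholds.
#' @param roi_masks optional named list of ROI masks.
#' @param verbose print stage messages.
#' @return list: \code{lag}, \code{isc} (pairwise maps), \code{group_fit},
#'   \code{isrsa} (per similarity kind: fit, similarity stat map, cluster
#'   table, optional ROI tables), \code{log}.
#' @export
run_imaging <- function(series_set, mask, behaviour, groups,
                        lag_tr = NULL, candidate_lags = 0:6,
                        censor_policy = "include",
                        p_voxel = 0.001, k_cluster = 20,
                        q_fdr = 0.05, k_roi = 5,
                        roi_masks = NULL, verbose = FALSE) {
  log <- character()
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  labels <- lapply(series_set, `[[`, "volume_labels")
  if (is.null(lag_tr)) {
    sel <- select_lag(series_set, mask, candidate_lags)
    lag_tr <- sel$lag_tr
    say("selected HRF lag ", lag_tr, " TRs by ISPC")
  }
  plan <- build_plan(labels, lag_tr = lag_tr)
  concat <- lapply(series_set, apply_plan, plan = plan)
  say("concatenated ", plan$n_retained, " volumes per subject")
  isc <- pairwise_isc(concat, mask, censor_policy = censor_policy,
                      censor = plan$censor)
  say(nrow(isc$pairs), " pairwise ISC maps over ",
      length(isc$voxel_index), " voxels")

  gcode <- group_code(groups)
  group_fit <- fit_cre_map(isc, cre_design(isc$pairs, group = gcode))

  sim_cur <- trial_similarity(behaviour$curiosity, "curiosity")
  sim_mem <- trial_similarity(behaviour$memory, "memory")
  sims <- list(
    curiosity_unique = residualize(sim_cur, sim_mem),
    memory_unique = residualize(sim_mem, sim_cur),
    annak_cmle = annak_similarity(behaviour$cmle)
  )
  isrsa <- lapply(names(sims), function(kind) {
    say("IS-RSA model: ", kind)
    des <- cre_design(isc$pairs, group = gcode,
                      similarity = grand_mean_centre(sims[[kind]]),
                      interaction = TRUE)
    fit <- fit_cre_map(isc, des)
    sm <- stat_map(fit, "similarity")
    clus <- cluster_threshold(sm, p_voxel = p_voxel, k = k_cluster)
    rois <- NULL
    if (!is.null(roi_masks)) {
      rois <- lapply(roi_masks, function(rm) {
        roi_fdr(sm, rm, q = q_fdr, k = k_roi)$table
      })
    }
    list(fit = fit, map = sm, clusters = clus$table, roi = rois)
  })
  names(isrsa) <- names(sims)
  list(lag = lag_tr, plan = plan, isc = isc, group_fit = group_fit,
       isrsa = isrsa, log = log)
}
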