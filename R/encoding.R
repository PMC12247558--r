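#' Mean-centre curiosity ratings within each subject
#'
#' Adds (or recomputes) \code{curiosity_centred} as the raw rating minus
#' that subject's mean rating, so every subject's centred ratings have
#' mean exactly zero. Idempotent on the centred column.
#'
#' @param table a trial table with \code{subject_id} and
#'   \code{curiosity_raw}.
#' @return the table with \code{curiosity_centred} set.
#' @export
centre_curiosity <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "curiosity_raw") %in% names(table)))
  miss <- which(is.na(table$curiosity_raw))
  if (length(miss)) {
    stop("missing curiosity ratings in rows: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }
  mu <- ave(table$curiosity_raw, table$subject_id)
  table$curiosity_centred <- table$curiosity_raw - mu
  table
}

#' Code a binary memory outcome at a confidence cutoff
#'
#' For recognition, a trial counts as remembered iff the chosen answer
#' was correct and reported confidence exceeds the cutoff (strict
#' inequality). Cutoff 0 reproduces recognition regardless of confidence
#' (confidence is at least 1); cutoff 3 is the high-confidence measure.
#' Cued recall ignores the cutoff.
#'
#' @param table trial table with \code{recognition_correct},
#'   \code{confidence} and \code{recall_correct}.
#' @param cutoff integer in 0..5.
#' @param measure \code{"recognition"} or \code{"recall"}.
#' @return integer 0/1 vector, one element per row.
#' @export
code_memory <- function(table, cutoff = 3,
                        measure = c("recognition", "recall")) {
  measure <- match.arg(measure)
  if (length(cutoff) != 1 || cutoff < 0 || cutoff > 5 || cutoff != round(cutoff)) {
    stop("cutoff must be an integer in 0..5", call. = FALSE)
  }
  if (measure == "recall") return(as.integer(table$recall_correct))
  stopifnot(all(table$confidence %in% 1:6))
  as.integer(table$recognition_correct == 1 & table$confidence > cutoff)
}

#' Fit the memory-encoding generalised linear mixed model
#'
#' Logistic mixed model predicting a binary memory outcome from the
#' within-subject centred curiosity rating, the effect-coded incentive
#' group and their interaction, with crossed random intercepts for
#' subject and stimulus. The full variant adds per-subject random
#' curiosity slopes (uncorrelated with the subject intercept); the
#' reduced variant omits them, mirroring the fallback used when the full
#' fit is singular. Estimation by Laplace-approximate maximum likelihood
#' via \pkg{lme4}.
#'
#' @param table trial table (see [simulate_behaviour()] for columns).
#' @param outcome binary 0/1 vector aligned with the rows of
#'   \code{table}, e.g. from [code_memory()].
#' @param variant \code{"full"} or \code{"reduced"}.
#' @param nAGQ passed to \code{lme4::glmer}; 1 (Laplace) by default.
#' @return a list of class \code{glme_fit}: \code{fixed_effects}
#'   (data.frame with \code{b}, \code{SE}, \code{z}, \code{p}),
#'   \code{random_sd}, \code{subject_slopes} (full variant only:
#'   fixed curiosity effect plus the subject's conditional-mode random
#'   slope), \code{converged}, \code{singular}, \code{model_variant},
#'   \code{n_dropped} (rows removed for missingness), \code{model}.
#' @export
fit_glme <- function(table, outcome, variant = c("full", "reduced"),
                     nAGQ = 1L) {
  variant <- match.arg(variant)
  stopifnot(length(outcome) == nrow(table), all(outcome %in% 0:1))
  d <- data.frame(
    y = as.integer(outcome),
    curiosity_centred = table$curiosity_centred,
    incentive_code = table$incentive_code,
    subject_id = table$subject_id,
    stimulus_id = table$stimulus_id
  )
  keep <- stats::complete.cases(d)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("dropping ", n_dropped, " rows with missing values")
    d <- d[keep, , drop = FALSE]
  }
  if (length(unique(d$incentive_code)) < 2) {
    stop("need subjects in both incentive groups", call. = FALSE)
  }
  d <- d[order(d$subject_id, d$stimulus_id), , drop = FALSE]

  form <- if (variant == "full") {
    y ~ curiosity_centred * incentive_code +
      (1 | subject_id) + (0 + curiosity_centred | subject_id) +
      (1 | stimulus_id)
  } else {
    y ~ curiosity_centred * incentive_code +
      (1 | subject_id) + (1 | stimulus_id)
  }
  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial(), nAGQ = nAGQ,
                control = lme4::glmerControl(calc.derivs = FALSE)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  converged <- length(fit@optinfo$conv$lme4) == 0
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_row <- is.na(vc$var2)
  random_sd <- stats::setNames(vc$sdcor[sd_row],
                               paste(vc$grp[sd_row], vc$var1[sd_row], sep = "."))
  singular <- lme4::isSingular(fit, tol = 1e-4) ||
    any(abs(vc$sdcor[!sd_row]) > 0.999, na.rm = TRUE)

  co <- summary(fit)$coefficients
  fixed <- data.frame(
    effect = rownames(co), b = co[, "Estimate"], SE = co[, "Std. Error"],
    z = co[, "z value"], p = co[, "Pr(>|z|)"], row.names = NULL
  )
  fixed$effect[fixed$effect == "(Intercept)"] <- "intercept"
  fixed$effect[fixed$effect == "curiosity_centred:incentive_code"] <-
    "curiosity_x_incentive"

  subject_slopes <- NULL
  if (variant == "full") {
    re <- lme4::ranef(fit)$subject_id
    b_cur <- fixed$b[fixed$effect == "curiosity_centred"]
    subject_slopes <- stats::setNames(
      b_cur + re[, "curiosity_centred"], rownames(re))
  }
  structure(list(
    fixed_effects = fixed, random_sd = random_sd,
    subject_slopes = subject_slopes, converged = converged,
    singular = singular, model_variant = variant, n_dropped = n_dropped,
    model = fit
  ), class = "glme_fit")
}

#' Extract mean-centred per-subject curiosity slopes (CMLE scores)
#'
#' The curiosity-motivated learning enhancement score of a subject is the
#' subject-specific slope linking curiosity to memory encoding, taken
#' from the full mixed model (fixed effect plus the conditional mode of
#' the subject's random slope) and mean-centred across subjects.
#'
#' @param fit a \code{glme_fit} with \code{model_variant = "full"}.
#' @return named numeric vector of centred scores (mean exactly 0).
#' @export
extract_cmle <- function(fit) {
  stopifnot(inherits(fit, "glme_fit"))
  if (fit$model_variant != "full" || is.null(fit$subject_slopes)) {
    stop("CMLE scores require the full model (random curiosity slopes)",
         call. = FALSE)
  }
  s <- fit$subject_slopes
  s - mean(s)
}
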