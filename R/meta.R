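#' Inverse-variance fixed-effect meta-analysis of one coefficient
#'
#' Pools unstandardised log-odds estimates of the same effect across data
#' collections by weighted least squares with weights \eqn{1/SE^2}:
#' \deqn{b = \sum w_k b_k / \sum w_k, \quad SE = 1/\sqrt{\sum w_k}.}
#'
#' @param estimates data.frame with columns \code{study_id},
#'   \code{effect_name}, \code{b}, \code{SE} (all rows the same effect).
#' @return one-row data.frame: \code{effect_name}, \code{b_pooled},
#'   \code{SE_pooled}, \code{z}, \code{p} (two-sided normal), \code{OR},
#'   \code{CI95_low}, \code{CI95_high}, plus attribute \code{weights}.
#' @export
fixed_effect_meta <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1,
            all(c("effect_name", "b", "SE") %in% names(estimates)))
  if (length(unique(estimates$effect_name)) != 1) {
    stop("all estimates must share one effect_name", call. = FALSE)
  }
  if (any(estimates$SE <= 0)) stop("SE must be > 0", call. = FALSE)
  w <- 1 / estimates$SE^2
  b <- sum(w * estimates$b) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- b / se
  or <- to_odds_ratio(b, se)
  out <- data.frame(
    effect_name = estimates$effect_name[1], b_pooled = b, SE_pooled = se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    OR = or$OR, CI95_low = or$CI95_low, CI95_high = or$CI95_high
  )
  attr(out, "weights") <- w
  out
}

#' Convert a log-odds estimate to an odds ratio with 95% CI
#'
#' \eqn{OR = e^b}, \eqn{CI = e^{b \pm 1.96\,SE}} (normal quantile).
#' Rounding to two decimals happens only at the report layer.
#'
#' @param b log-odds estimate.
#' @param SE its standard error (> 0).
#' @return data.frame with \code{OR}, \code{CI95_low}, \code{CI95_high}.
#' @export
to_odds_ratio <- function(b, SE) {
  if (any(SE <= 0)) stop("SE must be > 0", call. = FALSE)
  data.frame(OR = exp(b), CI95_low = exp(b - 1.96 * SE),
             CI95_high = exp(b + 1.96 * SE))
}

#' Regress pooled effects on the confidence cutoff
#'
#' Ordinary least squares of the integrated (meta-analytic) log-odds
#' estimates on the confidence cutoff, scaled 0 to 5 so the intercept is
#' interpretable as the effect at the laxest criterion. Inference from
#' the t distribution with \eqn{n - 2} degrees of freedom.
#'
#' @param pooled data.frame with columns \code{cutoff} (0..5, unique) and
#'   \code{b_pooled}.
#' @param weights optional per-cutoff weights for weighted least squares;
#'   default unweighted.
#' @return data.frame: \code{slope}, \code{CI95_low}, \code{CI95_high},
#'   \code{p}, \code{intercept}.
#' @export
cutoff_regression <- function(pooled, weights = NULL) {
  stopifnot(is.data.frame(pooled),
            all(c("cutoff", "b_pooled") %in% names(pooled)))
  if (anyDuplicated(pooled$cutoff)) {
    stop("duplicate cutoffs in pooled estimates", call. = FALSE)
  }
  if (nrow(pooled) < 3) {
    stop("cutoff regression needs at least 3 cutoffs", call. = FALSE)
  }
  fit <- stats::lm(b_pooled ~ cutoff, data = pooled, weights = weights)
  # an exactly linear sweep is a legitimate degenerate input; silence the
  # perfect-fit note rather than surfacing it to every caller
  co <- suppressWarnings(summary(fit))$coefficients
  ci <- suppressWarnings(stats::confint(fit, "cutoff", level = 0.95))
  data.frame(
    slope = co["cutoff", "Estimate"],
    CI95_low = ci[1], CI95_high = ci[2],
    p = co["cutoff", "Pr(>|t|)"],
    intercept = co["(Intercept)", "Estimate"]
  )
}
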