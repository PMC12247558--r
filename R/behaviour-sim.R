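#' Configuration for the behavioural trial simulator
#'
#' Describes the data-generating process for incidental memory encoding
#' under curiosity and a between-subject monetary incentive: a logistic
#' mixed model with crossed random intercepts for subject and stimulus and
#' a per-subject random slope for the (within-subject centred) curiosity
#' rating,
#' \deqn{logit P(y_{is} = 1) = \beta_0 + (\beta_C + b_i) c_{is} +
#'   \beta_I g_i + \beta_{CI} c_{is} g_i + u_i + v_s,}
#' where \eqn{c_{is}} is the centred curiosity rating, \eqn{g_i \in
#' \{-1, +1\}} the effect-coded group, \eqn{u_i, v_s, b_i} independent
#' normal random effects.
#'
#' @param n_subjects number of subjects; must be even (two equal groups).
#' @param n_stimuli number of stimuli seen by every subject.
#' @param intercept fixed intercept on the log-odds scale.
#' @param beta_curiosity fixed curiosity slope (log-odds per rating unit).
#' @param beta_incentive fixed incentive effect (log-odds per effect-coded
#'   unit, \eqn{-1} control / \eqn{+1} incentive).
#' @param beta_interaction fixed curiosity-by-incentive interaction.
#' @param sd_subject_intercept,sd_stimulus_intercept,sd_curiosity_slope
#'   standard deviations of the random effects (log-odds scale), all
#'   \eqn{\ge 0}.
#' @param sd_stimulus_curiosity standard deviation of a stimulus-level
#'   component shared across subjects in the curiosity ratings; raising it
#'   makes subjects' rating vectors more alike.
#' @param confidence_model list with elements \code{correct} and
#'   \code{incorrect}, each a probability vector over confidence levels
#'   1 to 6; the default gives a monotone confidence-accuracy association.
#' @param seed integer seed fixing all draws.
#' @return an object of class \code{behaviour_sim_config}.
#' @seealso [simulate_behaviour()]
#' @export
behaviour_sim_config <- function(n_subjects,
                                 n_stimuli = 36,
                                 intercept = 0,
                                 beta_curiosity = 0,
                                 beta_incentive = 0,
                                 beta_interaction = 0,
                                 sd_subject_intercept = 0,
                                 sd_stimulus_intercept = 0,
                                 sd_curiosity_slope = 0,
                                 sd_stimulus_curiosity = 0.8,
                                 confidence_model = NULL,
                                 seed = 1L) {
  if (n_subjects < 2 || n_subjects %% 2 != 0) {
    stop("n_subjects must be even (two equal incentive groups)", call. = FALSE)
  }
  sds <- c(sd_subject_intercept, sd_stimulus_intercept, sd_curiosity_slope,
           sd_stimulus_curiosity)
  if (any(sds < 0)) stop("random-effect SDs must be >= 0", call. = FALSE)
  if (is.null(confidence_model)) {
    confidence_model <- list(
      correct   = c(0.03, 0.05, 0.10, 0.17, 0.28, 0.37),
      incorrect = c(0.30, 0.26, 0.20, 0.13, 0.07, 0.04)
    )
  }
  stopifnot(length(confidence_model$correct) == 6,
            length(confidence_model$incorrect) == 6)
  confidence_model <- lapply(confidence_model, function(p) p / sum(p))
  structure(list(
    n_subjects = as.integer(n_subjects), n_stimuli = as.integer(n_stimuli),
    intercept = intercept, beta_curiosity = beta_curiosity,
    beta_incentive = beta_incentive, beta_interaction = beta_interaction,
    sd_subject_intercept = sd_subject_intercept,
    sd_stimulus_intercept = sd_stimulus_intercept,
    sd_curiosity_slope = sd_curiosity_slope,
    sd_stimulus_curiosity = sd_stimulus_curiosity,
    confidence_model = confidence_model, seed = as.integer(seed)
  ), class = "behaviour_sim_config")
}

#' Simulate a behavioural trial table
#'
#' Draws curiosity ratings (integers 1-7, a shared stimulus-level
#' component plus subject noise), assigns subjects to two balanced
#' incentive groups (effect-coded \eqn{-1}/\eqn{+1}), and generates
#' recognition, confidence (1-6) and cued-recall outcomes from the
#' configured logistic mixed model. Recognition and recall are drawn from
#' the same linear predictor with independent noise; confidence is drawn
#' from the configured correct/incorrect categorical distributions.
#' Per-subject trial orders are independent pseudo-random permutations of
#' the stimulus set.
#'
#' @param cfg a [behaviour_sim_config()].
#' @return a \code{data.frame} (trial table) with one row per subject by
#'   stimulus: \code{subject_id}, \code{stimulus_id},
#'   \code{presentation_index}, \code{curiosity_raw},
#'   \code{curiosity_centred}, \code{recognition_correct},
#'   \code{confidence}, \code{recall_correct}, \code{incentive_code}.
#'   Attribute \code{true_subject_slopes} carries the per-subject total
#'   curiosity slope (fixed + random) for parameter-recovery checks.
#' @export
simulate_behaviour <- function(cfg) {
  stopifnot(inherits(cfg, "behaviour_sim_config"))
  set.seed(cfg$seed)
  N <- cfg$n_subjects; S <- cfg$n_stimuli

  group <- rep(c(-1, 1), each = N / 2)
  u_subj <- rnorm(N, 0, cfg$sd_subject_intercept)
  v_stim <- rnorm(S, 0, cfg$sd_stimulus_intercept)
  b_slope <- rnorm(N, 0, cfg$sd_curiosity_slope)
  stim_curio <- rnorm(S, 0, cfg$sd_stimulus_curiosity)

  rows <- vector("list", N)
  for (i in seq_len(N)) {
    order_i <- sample.int(S)
    raw <- round(4 + stim_curio + rnorm(S, 0, 1.2))
    raw <- pmin(pmax(raw, 1L), 7L)
    centred <- raw - mean(raw)
    eta <- cfg$intercept + (cfg$beta_curiosity + b_slope[i]) * centred +
      cfg$beta_incentive * group[i] +
      cfg$beta_interaction * centred * group[i] + u_subj[i] + v_stim
    p <- plogis(eta)
    recog <- rbinom(S, 1, p)
    recall <- rbinom(S, 1, p)
    conf <- integer(S)
    for (s in seq_len(S)) {
      dist <- if (recog[s] == 1) cfg$confidence_model$correct else
        cfg$confidence_model$incorrect
      conf[s] <- sample.int(6, 1, prob = dist)
    }
    rows[[i]] <- data.frame(
      subject_id = sprintf("sub-%03d", i),
      stimulus_id = sprintf("stim-%02d", seq_len(S)),
      presentation_index = order(order_i),
      curiosity_raw = raw,
      curiosity_centred = centred,
      recognition_correct = recog,
      confidence = conf,
      recall_correct = recall,
      incentive_code = group[i]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "true_subject_slopes") <-
    stats::setNames(cfg$beta_curiosity + b_slope, sprintf("sub-%03d", seq_len(N)))
  out
}
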