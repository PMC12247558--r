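#!/usr/bin/env Rscript
# Generate the three behavioural data collections (two online studies and
# the scanner sample) from the logistic mixed data-generating process,
# with a common curiosity effect, a weaker incentive effect, and
# subject-varying curiosity slopes. Writes one trial table per study.

suppressMessages(library(curisc))

out_dir <- "results/behaviour"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

# sample sizes mirror the two web samples and the scanner sample
# (balanced groups; the generator requires an even N)
studies <- list(study1 = 78L, study2 = 78L, fmri = 50L)

for (st in names(studies)) {
  cfg <- behaviour_sim_config(
    n_subjects = studies[[st]], n_stimuli = 36,
    intercept = -0.3,
    beta_curiosity = 0.08, beta_incentive = 0.08, beta_interaction = 0,
    sd_subject_intercept = 0.5, sd_stimulus_intercept = 0.3,
    sd_curiosity_slope = 0.15,
    seed = seed + match(st, names(studies)))
  tab <- simulate_behaviour(cfg)
  write_trial_table(tab, file.path(out_dir, paste0(st, "_trials.tsv")))
  write_sidecar(file.path(out_dir, paste0(st, "_trials.json")),
                unclass(cfg), cfg$seed)
  cat(sprintf("%s: %d subjects x %d stimuli, P(recognition) = %.3f\n",
              st, studies[[st]], 36, mean(tab$recognition_correct)))
}
cat("trial tables written to", out_dir, "\n")
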