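# curisc

Curiosity, incentives, and intersubject correlation: an R package for
analysing incidental memory encoding during naturalistic viewing, in two
arms that share one question — what makes some events stick?

**Who it is for.** Researchers running (or re-analysing) paradigms where
participants watch identical time-locked stimuli, rate their curiosity,
and take a surprise memory test later — with or without a monetary
incentive group — and who want the full statistical chain from trial
tables and 4D volumes to integrated coefficients and thresholded brain
maps, testable end-to-end on synthetic data with known ground truth.

## What it computes

**Behavioural arm.** A logistic mixed model predicts each trial's memory
outcome from the within-subject centred curiosity rating $c_{is}$, the
effect-coded incentive group $g_i$, and their interaction, with crossed
random intercepts for subject and stimulus and random curiosity slopes:

    logit P(y_is = 1) = b0 + (bC + b_i) c_is + bI g_i + bCI c_is g_i + u_i + v_s

Coefficients from separate data collections are pooled by
inverse-variance fixed-effect meta-analysis and reported as odds ratios;
a confidence-cutoff sweep (recognition with confidence > 0 … > 5)
regresses the pooled effect on the cutoff. Per-subject curiosity slopes,
mean-centred, are the CMLE scores (curiosity-motivated learning
enhancement) passed to the imaging arm.

**Imaging arm.** Per-subject 4D series are reduced to stimulus volumes,
reordered to a canonical stimulus order, and shifted by a haemodynamic
lag selected via intersubject pattern correlation. Every unordered
subject pair then yields a voxelwise Fisher-z ISC map. Those pair maps
are modelled with a linear mixed model with crossed random intercepts
for the two subjects of each pair,

    z_ij = x_ij' beta + u_i + u_j + e_ij,   u ~ N(0, tau2), e ~ N(0, sigma2)

fitted by REML (spectral profiling of tau2/sigma2, authored in this
package), with fixed effects for the pair group code (+1/0/−1),
behavioural similarity (trial-vector correlation, residualised unique
variants, or the Anna-Karenina pair mean for CMLE) and their
interaction. Voxelwise p-values use Satterthwaite degrees of freedom.
Inference is whole-brain cluster-extent thresholding (p < 0.001,
face-adjacency components, k ≥ 20) and within-ROI Benjamini–Hochberg FDR
(q = 0.05, k ≥ 5), plus an optional subject-level permutation null for
the maximum cluster size.

**Synthetic data.** `simulate_behaviour()` and `simulate_fmri()`
generate both arms' inputs from known parameters (shared
stimulus-locked signal + idiosyncratic signal + noise, so expected ISC
is a closed-form variance ratio), which is how the whole pipeline is
tested without any data download.

## Worked example

The `analysis/` scripts run the two arms over synthetic data at desk
scale. `01_simulate_behaviour.R` writes three trial tables (two web
samples of 78, a scanner sample of 50), then `02_fit_behavioural.R`
fits, pools and sweeps:

```
Integrated effects (high-confidence recognition):
           effect_name                                        report
     curiosity_centred   0.073 (0.020)  OR 1.08 [1.03; 1.12]  z=3.60
        incentive_code   0.055 (0.041)  OR 1.06 [0.97; 1.15]  z=1.34
 curiosity_x_incentive -0.028 (0.019)  OR 0.97 [0.94; 1.01]  z=-1.50
```

The generating truth was bC = bI = 0.08 with no interaction: the pooled
log-odds land on it within one standard error, and the odds ratio reads
as an 8% increase in the odds of encoding per rating point. (The
generator holds the curiosity effect constant across confidence levels,
so the sweep's slope is near zero by design.)

`03_simulate_fmri.R` plants 16 subjects on a 12³ grid with a 4-TR
haemodynamic delay and an Anna-Karenina score that scales idiosyncratic
amplitude ("low scorers are alike"); `04_imaging_isrsa.R` recovers the
chain:

```
Selected lag: 4 TRs; 120 pairwise maps over 594 volumes
Mean pairwise ISC: 0.461
curiosity_unique: 0 whole-brain cluster(s), 0 ROI cluster(s)
memory_unique: 0 whole-brain cluster(s), 0 ROI cluster(s)
annak_cmle: 1 whole-brain cluster(s), 1 ROI cluster(s)
```

The two behavioural similarities had no built-in brain link (correctly
empty), while the planted CMLE effect surfaces as one widespread
negative cluster — negative because low scorers resembling each other
means pair similarity falls as the pair-mean score rises.
`05_permutation_threshold.R` adds the permutation-based extent
threshold on a reduced mask.

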