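---
title: "Models and methods behind curisc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind curisc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`curisc` implements a two-armed analysis of incidental memory encoding
under curiosity and monetary incentives: a behavioural arm built on
logistic mixed models and fixed-effect meta-analysis, and an imaging arm
built on intersubject correlation (ISC) and intersubject
representational similarity analysis (IS-RSA) for naturalistic fMRI.
This vignette explains the models, the tunable parameters, the
synthetic-data generators the test suite runs on, and the numerical and
design choices that were genuinely open.

## The behavioural arm

### Memory coding

Recognition responses are dummy-coded against the correct answer and
combined with a 1–6 confidence rating. At cutoff $c$ a trial counts as
remembered iff the answer was correct *and* confidence exceeds $c$
(strict inequality). Cutoff 0 therefore reproduces recognition
regardless of confidence, and cutoff 3 defines the high-confidence
measure that is used for CMLE extraction and the behavioural similarity
matrices. Cued recall is a separate 0/1 outcome that ignores confidence.
Prevalence is weakly monotone non-increasing in the cutoff by
construction, which the suite checks.

### The generalised linear mixed model

For subject $i$, stimulus $s$, centred curiosity rating $c_{is}$
(ratings are mean-centred within each subject, so each subject's centred
ratings sum to exactly zero) and effect-coded group
$g_i \in \{-1, +1\}$:

$$\mathrm{logit}\,P(y_{is}=1) = \beta_0 + (\beta_C + b_i)\,c_{is}
  + \beta_I g_i + \beta_{CI}\,c_{is} g_i + u_i + v_s,$$

with independent normal random effects: subject intercepts $u_i$,
stimulus intercepts $v_s$ and, in the full variant, subject-specific
curiosity slopes $b_i$ (uncorrelated with the subject intercept; the
correlation is not identifiable at the sample sizes involved and the
generator draws them independently). Estimation is Laplace-approximate
maximum likelihood through `lme4::glmer`. A fit is flagged singular when
any random-effect standard deviation drops below $10^{-4}$ or an
estimated correlation exceeds 0.999 in magnitude; the pipeline then
refits the reduced variant (no random slopes) for the meta-analytic
coefficients, mirroring the fallback used in practice when full fits are
degenerate.

CMLE (curiosity-motivated learning enhancement) scores are the
per-subject curiosity slopes — fixed effect plus the conditional mode of
the subject's random slope — mean-centred across subjects. Whether the
fixed effect is included or not is immaterial downstream: mean-centring
removes any constant, so the Anna-Karenina similarity geometry is
identical either way. CMLE always comes from a full fit, because random
slopes are what define it; a slope variance estimated at zero simply
yields all-zero scores.

### Meta-analysis and the confidence-cutoff sweep

Per-effect coefficients from the separate data collections are pooled by
inverse-variance weighted least squares,
$b = \sum_k w_k b_k / \sum_k w_k$ with $w_k = 1/SE_k^2$ and
$SE = (\sum_k w_k)^{-1/2}$, i.e. a fixed-effect meta-analysis. No
heterogeneity model is fitted — the three collections use one paradigm —
and odds ratios are $e^b$ with $e^{b \pm 1.96\,SE}$ intervals (normal
quantile; rounding to two decimals happens only in report strings).

The quality-of-memory sweep refits the model at every cutoff 0–5, pools
per cutoff, and regresses the pooled coefficient on the cutoff by
ordinary least squares with $t_{n-2}$ inference. The cutoff axis is kept
on its natural 0–5 scale so the intercept is the effect at the laxest
criterion. Weighting this regression by the pooled standard errors is
supported (`weights`) but off by default: the estimates being regressed
already come from a weighted pooling, and the plain linear model treats
each cutoff as one observation.

## The imaging arm

### Volume selection, reordering, lag

Each subject's acquisition interleaves mock prefixes, trick (stimulus)
windows, fixations and rating periods, in a subject-specific
pseudo-random stimulus order; stimulus onsets are aligned to volume
boundaries. The concatenation plan (a) keeps only trick volumes, (b)
groups them by stimulus in a canonical order shared by all subjects, and
(c) shifts every window forward by an integer lag $L$ so the delayed
haemodynamic response is captured: the $L$ volumes after the window
replace its first $L$. The shift is an index shift within the
acquisition, never circular — the jittered fixation and rating periods
that follow each trick guarantee the shifted indices exist, and the plan
errors if they do not. Volumes are copied, never interpolated.

The lag is chosen by intersubject pattern correlation (ISPC): for each
candidate lag, the spatial correlation of masked voxel patterns is
computed at every retained time point for every subject pair and
averaged; the arg-max lag wins, and the full score table is returned so
the flatness of the profile can be inspected. The exact published ISPC
formulation lives in supplementary material we treat as unavailable;
time-point-wise spatial correlation averaged over time and pairs is this
package's documented choice.

The group grey-matter mask includes a voxel iff it is grey matter in at
least 50% of subjects (inclusive threshold, so exactly half qualifies).

### Pairwise ISC and behavioural similarity

For every unordered pair and voxel, Pearson correlation over the
concatenated volumes, clipped to $\pm(1-10^{-7})$ and Fisher
z-transformed ($z = \mathrm{atanh}\,r$). The clip keeps $z$ finite at
machine-perfect correlation with negligible bias elsewhere.
Zero-variance voxels inside the mask produce $z = 0$ with a recorded
count rather than NaN, preserving array geometry. Censored volumes are
included by default (they arrive zeroed or interpolated from upstream
preprocessing conventions); `censor_policy = "pairwise-drop"` instead
drops any volume censored in either member of a pair.

Behavioural similarity between subjects is the Fisher-z-transformed
correlation of trial vectors (centred curiosity ratings, or the
high-confidence memory dummy) aligned to the canonical stimulus order. A
zero-variance vector — a subject who remembered everything — yields
similarity 0 for its pairs, with a warning, so the pair index survives.
Unique-curiosity and unique-memory matrices are the residuals of one
similarity regressed on the other (OLS with intercept over pairs); the
residuals are orthogonal to the covariate to machine precision and the
operation is a projection (idempotent).

CMLE has one value per subject rather than a trial course, so its pair
similarity uses the Anna-Karenina form: the mean of the two subjects'
scores. The sign of the fitted brain–behaviour slope then distinguishes
"high scorers are alike" (positive) from "low scorers are alike"
(negative). The generator supports both generative directions via
`annak_direction`, because the direction is a hypothesis, not a fact of
the method; the analysis scripts use `"low_alike"` and correctly recover
a negative effect. Group is deviation-coded $\pm 0.5$ per subject and
summed per pair, giving $1/0/-1$; behavioural similarity is grand-mean
centred before the interaction term is formed so the group main effect
keeps its interpretation.

### The crossed random-effects model

Every voxel's pair values are modelled as

$$z_{ij} = x_{ij}^\top \beta + u_i + u_j + e_{ij}, \qquad
  u_k \sim N(0, \tau^2),\; e_{ij} \sim N(0, \sigma^2),$$

with one shared variance $\tau^2$ for both members of a pair (subjects
are exchangeable). Estimation is REML: with $K = ZZ^\top$ the
pair–subject incidence Gram matrix, $V = \sigma^2(I + \lambda K)$ where
$\lambda = \tau^2/\sigma^2$. $K$ is eigendecomposed once per design;
rotating the response and design into its eigenbasis makes $V$ diagonal,
so each voxel costs one one-dimensional profile optimisation of
$\lambda$ (on a log scale, with the boundary $\tau^2 = 0$ reported as a
valid estimate, not an error) plus weighted least squares. The suite
verifies the optimum against a dense brute-force REML likelihood with
the explicit covariance $\sigma^2 I + \tau^2 ZZ^\top$, and the exact OLS
limit at $\tau^2 = 0$.

**Degrees of freedom.** Inference defaults to a $t$ reference with
Satterthwaite-approximated degrees of freedom, computed analytically
from the REML information matrix in the same rotated basis. This is a
deliberate choice: the regressors of interest are built from $N$ subject
scores, not from $N(N-1)/2$ independent pairs, and their effective
degrees of freedom are on the order of $N$ (about 18 at $N = 20$ in the
suite's measurements). A plain normal reference is anticonservative at
these sample sizes — its voxelwise $p < 0.001$ exceedance ran near
0.005 instead of 0.001 in null simulations — while the Satterthwaite
reference is calibrated. `df_method = "normal"` restores the
large-sample normal reference for comparability with tools that use it.

### Thresholding

Whole-brain: voxels with two-sided $p < 0.001$ are labelled by connected
components under face adjacency (first-nearest-neighbour; edge- or
corner-touching voxels are separate), separately for positive and
negative statistics, and components with at least $k = 20$ voxels are
kept (inclusive extent rule). Within a priori ROIs: Benjamini–Hochberg
FDR at $q = 0.05$ over the ROI's voxels, then the same face-adjacency
clustering with $k = 5$. Both $k$ values are configuration parameters;
the package provides, as an alternative to externally calibrated extent
thresholds, a permutation null that permutes the *subject-level*
behavioural scores and rebuilds pair similarity before every refit —
permuting raw pair rows would break the crossed dependence structure and
is deliberately not offered.

## The synthetic generators

The behavioural generator draws curiosity ratings as integers 1–7 from a
shared stimulus-level component (`sd_stimulus_curiosity`, default 0.8 on
the rating scale — enough to make rating vectors correlate across
subjects without saturating) plus subject noise, assigns balanced
effect-coded groups, and draws recognition and recall from the logistic
model above. Confidence comes from two categorical distributions over
1–6, one for correct and one for incorrect trials, monotone by default.
Note the generator does not make the *curiosity effect itself* grow with
confidence — the confidence channel is independent of curiosity given
correctness — so a flat cutoff sweep is the expected result on synthetic
data, and the sweep machinery is validated on exact linear inputs
instead.

The fMRI generator composes every voxel's trick-window signal from a
stimulus-locked component shared by all subjects, an idiosyncratic
component (optionally amplitude-scaled by normalised Anna-Karenina
scores in either direction), and white noise; volumes of no interest
carry noise only. The expected pairwise ISC has the closed form
$\sigma^2_{shared}/(\sigma^2_{shared}+\sigma^2_{idio}+\sigma^2_{noise})$,
which the suite verifies by Monte-Carlo at increasing series lengths.
The haemodynamic delay is an integer-TR shift of the stimulus-locked
component — there is deliberately no HRF convolution, physiological
noise, spatial autocorrelation or motion, so passing tests demonstrate
the statistical machinery, not robustness to real-data artefacts.
Defaults: 36 stimuli, a 12×12×12 grid (desk-scale; large enough for
extent thresholds to bite), TR 2 s, trick windows of 16–17 volumes when
a 594-volume concatenated series is wanted.

## Problem sizes and determinism

The suite and the acceptance script run at desk scale by choice: 200
subjects × 36 trials for behavioural recovery, 10 subjects at 594
concatenated volumes for ISC recovery, 20 subjects on a 12³ grid for
voxelwise null calibration, 20 seeded runs for lag recovery, 200
replicates for interval coverage. Every generator output is a pure
function of its configuration and seed, and reruns are byte-identical.
Slope recovery at 200×36 has a sampling standard deviation near 0.03 —
most of it the realised mean of the random slopes, $0.2/\sqrt{200}$ —
which is why the acceptance script reports a small Monte-Carlo average
rather than a single draw.

## Known limitations

- The gLME backend's Laplace approximation can be mildly biased for
  binary outcomes at few stimuli per subject; the suite's tolerances
  absorb this.
- The Satterthwaite computation adds roughly 3 ms per voxel at
  $N = 20$; for very large masks with `df_method = "normal"` wanted
  anyway, switching it off halves map-fit time.
- No spatial model links neighbouring voxels; cluster inference relies
  on extent thresholds or the permutation null.
- The IS-RSA similarity matrices treat behavioural measurements as
  error-free regressors; attenuation from estimating CMLE with few
  trials is not corrected.
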