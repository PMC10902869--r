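---
title: "Modeling choice history biases and their adaptation to sequential regularities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling choice history biases and their adaptation to sequential regularities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histbias)
```

## The problem

In two-alternative forced-choice (2AFC) perception, observers' decisions are
biased by their recent stimulus and choice history even when the task makes
trials independent. When the environment actually contains sequential
structure — here, a stimulus orientation that repeats from trial to trial
with probability 0.8 instead of 0.5 — such history biases become useful, and
observers adapt them. `histbias` provides the full computational pipeline
for studying this adaptation: session design, stimulus synthesis, a
generative observer for synthetic data, a lasso-regularized history-bias
regression, an orientation-energy reverse-correlation analysis that
dissociates *stimulus-independent decision bias* from *stimulus-dependent
sensitivity* (a perceptual confirmation bias), and the group-level
statistics used to summarize the effects.

## Session design

A session is 12 blocks of 100 trials: six blocks in a **neutral**
environment followed — always in this order, to avoid carry-over of learned
biases — by six blocks in a **repeating** environment. Stimuli are gratings
tilted ±45° from vertical at one of six Michelson contrasts
(0, 0.02, 0.04, 0.06, 0.12, 0.18), each presented equally often within each
environment.

* **Neutral**: the sequence of the 12 conditions (2 orientations × 6
  contrasts) is serially counterbalanced so that every condition is preceded
  equally often by every other condition. We construct this as an Eulerian
  path on the complete directed multigraph over the conditions (self-loops
  included). For 600 trials the 599 transitions cannot divide evenly over
  the 144 ordered pairs, so edge multiplicities are m or m+1; the extra
  edges are allocated with equal out- and in-degree per condition, which
  yields transition counts differing by at most 1 *and* exactly equal
  condition counts. Candidate sequences are resampled until the orientation
  repetition frequency is within ±0.02 of 0.5.
* **Repeating**: orientations are drawn sequentially with repetition
  probability `p_rep = 0.8`; whole sequences are resampled (incrementing the
  seed) until the empirical repetition frequency is within ±0.02 of the
  target. Contrasts are drawn as a balanced permutation independent of the
  orientation chain. The chain runs over *all* trials, including 0%-contrast
  ones: on those trials the rewarded response is the latent chain
  orientation, so the sequential regularity extends to trials without a
  target. In the neutral environment the 0%-contrast reward is uniform,
  pinning accuracy there at 50% for any observer. Block boundaries do not
  reset the chain; the chain restarts at the environment switch, because the
  two environments are analyzed separately.

The ≤1-count transition-balance rule is our reading of "preceded equally
often" for trial counts that do not divide the number of transition types;
exact balance is impossible at 600 trials.

## Stimuli and orientation energy

Stimuli are sinusoidal gratings (1 cycle/degree, random phase) embedded in
Gaussian white noise that is smoothed with a Gaussian kernel of SD 0.08° and
scaled so that the smoothed-noise SD equals 0.3 relative to the mean-gray
background (this RMS convention for "noise contrast 0.3" is a package
choice, recorded in `stimulus_params()`). The composite is windowed by a
raised-cosine circular aperture of radius 5° and clipped to [0, 1]. The
default raster is 24 px/° (240 × 240); analyses that need thousands of
stimuli use a reduced 64 × 64 raster (6.4 px/°), still comfortably above the
Nyquist limit for the highest filter frequency (1.4 c/° needs > 2.8 px/°).

Orientation energy is measured with a quadrature Gabor bank: 180
orientations (−89° to 90°, step 1°) × 9 spatial frequencies (0.6–1.4 c/°,
step 0.1, i.e. the target frequency ± 0.4). Each cell holds an even and an
odd filter sharing a raised-cosine envelope identical to the stimulus
aperture — this keeps orientation bandwidth comparable across frequencies —
DC-removed and normalized to unit L2 norm. The energy of a cell is
`sqrt(c² + s²)` of the two whole-aperture inner products with the
mean-subtracted raster: a single matched-aperture projection rather than a
spatial convolution map, appropriate because the stimulus is a full-field
aperture grating. This makes the measure phase-invariant (checked to < 1%
across phases) and invariant to constant luminance offsets. The frequency
range ends at 1.4 c/° to match the target-frequency ± 0.4 parenthetical used
in all summary averaging.

## The generative observer

The synthetic observer responds clockwise with probability

    P(CW) = λ_cw + (1 − λ_cw − λ_ccw) · σ(η)
    η = β₀ + β_c · c_signed
        + Σ_{k=1..7} w_stim[k]·s_{t−k} + Σ_{k=1..7} w_choice[k]·r_{t−k}
        + β_E · (g_cw · Z[E_cw] − g_ccw · Z[E_ccw])   (0%-contrast trials)

with σ the logistic function, `c_signed` the signed Michelson contrast,
`s`, `r` the ±1 stimulus and choice signs of the previous seven trials
(zero-padded at the start of each environment, never crossing the
environment switch), and the energy term active only on 0%-contrast trials:
`E_cw`/`E_ccw` are class-mean orientation energies (clockwise cells 1°–89°,
counterclockwise −89°–−1°, all frequencies), z-scored within environment,
and `g` assigns `gain_consistent` to the channel matching the *predicted*
orientation — the previous trial's stimulus orientation — and
`gain_inconsistent` to the other. With equal gains and `energy_beta = 0`
the observer reduces exactly to the history-logistic model.

Choices that were genuinely open, and how we resolved them:

* Lapses enter generatively as asymptotes (the standard psychometric
  convention); the fitting side estimates the same asymptote form by grid
  search (below). The two conventions agree at small lapse rates.
* The generative law combining history and gated energy sensitivity is
  additive in log-odds with multiplicative channel gains. This is a modeling
  choice used only for synthetic data and recovery testing; nothing
  downstream assumes it.
* "Predicted orientation" is the previous *stimulus*, not the previous
  response, matching how the reverse-correlation analysis conditions its
  data.

Default parameters are chosen to mimic a competent adult observer at these
contrasts: slope 15 log-odds per contrast unit (≈ 94% correct at the
highest contrast), lapse rates 0.02 per side, geometrically decaying history
kernels (lag-1 stimulus weight 0.25, choice weight 0.15, decay 0.5 per
lag). For observers whose 0%-contrast decisions are energy-driven we use
`energy_beta = 1`, making noise energy a major determinant of those choices
— consistent with observers showing robust sensitivity to noise-driven
orientation energy — and gains 1.5/0.5 for a clearly gain-asymmetric
(confirmation-bias) observer.

## History-bias regression

Per participant and environment we fit

    P(CW) = γ_cw + (1 − γ_cw − γ_ccw) · σ(Xβ)

where X holds an intercept, the current signed contrast (raw, not
z-scored), and the 14 history regressors `s_{t−1..7}`, `r_{t−1..7}`. The
first seven trials of an environment are excluded (no complete lags), as
are trials with a missing response; missed responses still occupy lag
positions with a 0 choice code (a neutral, configurable choice — the
convention for missed trials inside lags is not dictated by the design).

An L1 penalty λ = 0.001 — applied per observation, on the raw ±1 /
contrast-unit columns — shrinks the 14-dimensional history block only; the
intercept, contrast slope, and lapse rates are unpenalized. Whether λ
should be rescaled by sample size or applied to standardized columns is a
convention; ours is recorded in the fit metadata. Lapse rates are selected
by a bounded grid search over [0, 0.2] at 0.01 resolution, run
coarse-to-fine (0.04-step scan, then a 0.01-step refinement around the
optimum) with warm starts, selecting by penalized likelihood — the joint
problem is non-convex in the asymptotes, and the grid keeps the inner
problem well-behaved. Each inner problem is solved by penalized Fisher
scoring: the asymptote model is a binomial GLM with a non-canonical inverse
link, so each step is a weighted lasso least-squares problem solved by
coordinate descent with soft-thresholding, with step halving on the exact
penalized objective. Convergence is declared at a relative objective change
below 1e-8 (at most 10⁴ iterations, deterministic initialization at zero);
at λ = 0 the solution matches `glm`, and at fixed zero lapses it matches
`glmnet` to ~1e-7 (both verified in the test suite). Complete separation is
flagged and the fit marked non-converged; weights are still returned.

Derived summaries use the identity that, under ±1 coding, the sum of the
lag-k stimulus and choice weights equals the weight of a
previous-*correct*-choice regressor (and their difference the
previous-incorrect weight). Adaptation is the repeating-environment
previous-correct weight minus the neutral one. The recovery simulation
simulates 100 response sets from known parameters on the repeating
sequence — where current and previous stimuli are correlated — refits
each, and compares mean refits to the generating values, verifying that
the regularized model remains unbiased under that correlation.

## Reverse correlation

Restricted to 0%-contrast trials (asserted on input), conditioned on
environment × previous stimulus orientation. Energies are z-scored per
(orientation, frequency, participant, previous stimulus, environment) group
with the sample-SD convention; zero-variance cells are dropped and logged.
Each cell is fit with a maximum-likelihood logistic regression of the
clockwise-response indicator on the z-scored energy — `β₀` is the
stimulus-independent bias, `β₁` the stimulus-dependent sensitivity. The
1620 cells of a condition are fit in one vectorized Newton pass (equal to
`glm` to numerical precision; tested). Separation is flagged, estimates
truncated at |β| = 10 and excluded from summaries — numerical hygiene for
the small per-condition trial counts this design produces.

Outliers are then removed per (previous stimulus, environment) pool across
participants, orientations and frequencies with Tukey fences (1.5 × IQR;
quartiles by linear interpolation, `stats::quantile` type 7 — the fence
convention is quartile-sensitive, so it is recorded in the output
metadata). Bias is the mean `β₀` over all orientations and frequencies;
sensitivity is the mean `β₁` within the clockwise (1°–89°) and
counterclockwise (−89°–−1°) classes — 0° and 90° belong to neither class
but do contribute to the bias average, which we read as covering all
orientations. The *history effect on sensitivity* is, per environment, the
sensitivity to clockwise energy after a clockwise previous stimulus minus
after a counterclockwise one: positive values mean information consistent
with the prediction is amplified relative to inconsistent information.

## Group statistics

Paired t tests, Welch's t tests, 1–3-factor repeated-measures ANOVA (all
factors two-level, so every F has numerator df 1 and sphericity corrections
are unnecessary), and Spearman/Pearson correlations wrap the corresponding
`stats` routines and return tidy one-row-per-effect tables. Bayes factors
are out of scope. Learning-rate metrics (intercept and slope of a linear
fit to a history-weight trajectory, abscissa 0 at the first trial of the
environment) are provided; because trial-resolved state-space weight
estimation is out of scope, trajectories come from per-block refits of the
history model (`block_history_trajectory()`), which is labeled as a coarse
block-resolved stand-in in its output metadata.

## What the synthetic data do and do not show

The generator reproduces the design (transition statistics, contrast
balance, reward rules), a psychometric observer with lapses and history
kernels, and a prediction-gated sensitivity to noise energy. It does *not*
emulate reaction times, within-environment learning dynamics (generative
kernels are stationary; adaptation is induced by comparing environments),
monitor nonlinearities, or trait covariates. Passing tests therefore
demonstrate that the pipeline is correct and that its effects are
recoverable at realistic scales — not that any particular empirical result
holds in human data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at the scales the design
prescribes where feasible: 600-trial environments, 100-simulation
recoveries, and ~300 zero-contrast trials per previous-stimulus condition
for the reverse-correlation dissociation, at the reduced 64 × 64 raster
with the full 180 × 9 bank. Chance-level checks use 10⁵-trial simulations.
Degenerate inputs (single response class, constant energies, zero-variance
pools, too-short trajectories) are rejected or flagged rather than
silently absorbed; the relevant conventions (quartile type, missed-response
coding, noise-contrast definition) are configurable and recorded in
outputs.

## Known limitations

* Lapse rates are weakly identified at 600 trials per environment; the
  selected asymptotes can differ noticeably from generating values while
  history weights remain accurate (the recovery simulation quantifies
  this).
* The Gabor envelope and bandwidth are convention choices; the
  aperture-envelope used here is principled but not unique, and absolute
  energy units are therefore implementation-specific (z-scoring removes
  this dependence in all downstream analyses).
* The counterbalancing algorithm guarantees ≤1 transition-count imbalance,
  which is one defensible reading of serial counterbalancing at this trial
  count.
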