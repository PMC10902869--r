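# histbias

Simulation and analysis of **choice history biases** in two-alternative
forced-choice (2AFC) orientation discrimination, and of how those biases
**adapt to sequential regularities** in the stimulus stream.

## The problem

Perceptual decisions are biased by recent stimuli and choices even when
trials are independent. `histbias` implements the full pipeline for studying
what happens when the environment actually *has* sequential structure: a
session of 12 blocks × 100 trials in which gratings tilted ±45° from
vertical (six Michelson contrasts: 0, 0.02, 0.04, 0.06, 0.12, 0.18,
embedded in smoothed white noise) first repeat with probability 0.5
(*neutral*, serially counterbalanced) and then with probability 0.8
(*repeating*, Markov sequence). On 0%-contrast trials the rewarded response
is random in the neutral environment (pinning accuracy at 50%) but follows
the latent sequence in the repeating environment, so adapted history biases
pay off.

Two models sit at the core:

1. **History-bias regression** — a lasso-regularized logistic model of the
   probability of responding clockwise,

   `P(CW) = γ_cw + (1 − γ_cw − γ_ccw) · σ(β₀ + β_c·c_signed + Σₖ w_s[k]·s_{t−k} + Σₖ w_r[k]·r_{t−k})`,

   with lapse rates γ, signed contrast `c_signed`, and ±1-coded stimulus and
   choice regressors over the previous seven trials (penalty λ = 0.001 on
   the history block only). Under this coding, `w_s[k] + w_r[k]` is the
   *previous-correct-choice* weight; its repeating-minus-neutral difference
   is the **adaptation** of the history bias.

2. **Orientation-energy reverse correlation** — on 0%-contrast trials, the
   stimulus's orientation energy `E` (quadrature Gabor bank: 180
   orientations × 9 spatial frequencies, 0.6–1.4 c/°) predicts the response
   per cell: `P(CW) = σ(β₀ + β₁·Z[E])`, conditioned on environment ×
   previous stimulus. Averaging β₀ (all orientations) and β₁ (clockwise
   1°–89° vs counterclockwise −89°–−1° classes) after 1.5 × IQR outlier
   removal separates a *stimulus-independent decision bias* from a
   *stimulus-dependent sensitivity* whose modulation by the predicted
   orientation is a perceptual confirmation bias.

A generative observer (`observer_params()`, `simulate_session()`) with
psychometric, lapse, history-kernel and prediction-gated energy-gain
components provides synthetic data for parameter-recovery and dissociation
tests.

## Worked example

```r
library(histbias)

design <- build_session(seed = 7)
design
#> session design: 1200 trials, 12 blocks (6 per environment)
#>   contrasts: 0, 0.02, 0.04, 0.06, 0.12, 0.18
#>   repeating p_rep target 0.80 +/- 0.02

# an observer whose history kernels exploit the repeating structure
observer <- observer_params(w_stim = history_kernel(0.4),
                            w_choice = history_kernel(0.25))
behavior <- simulate_session(observer, design, seed = 108)

acc <- accuracy_summaries(behavior)
acc$by_contrast_env[acc$by_contrast_env$contrast == 0, ]
#>  participant_id environment contrast   n accuracy
#>           sim01     neutral        0 100     0.49
#>           sim01   repeating        0 100     0.59

fit_neutral   <- fit_history_model(build_design_matrix(behavior, "neutral"))
fit_repeating <- fit_history_model(build_design_matrix(behavior, "repeating"))
summ <- derive_history_summaries(fit_neutral, fit_repeating)
round(summ[1:3, c("lag", "prev_correct_neutral",
                  "prev_correct_repeating", "adaptation")], 3)
#>  lag prev_correct_neutral prev_correct_repeating adaptation
#>    1                0.755                  0.882      0.127
#>    2                0.414                  0.174     -0.240
#>    3                0.243                  0.335      0.092
```

The 0%-contrast accuracy shows the signature of useful history biases:
chance (0.49) in the neutral environment, where the reward is random, but
0.59 in the repeating environment, where following the sequence pays.
The lag-1 previous-correct weight is positive in both environments
(generating value 0.65); single-session estimates carry sampling noise of
roughly ±0.2, which is why group analyses and the 100-simulation recovery
procedure (`recovery_simulation()`) average over many fits.

The reverse-correlation side is driven by `reverse_correlation()` on the
energies of the 0%-contrast stimuli (`build_filter_bank()`,
`compute_energy_profiles()`); `run_end_to_end()` chains every stage for a
cohort of synthetic participants and writes tidy CSVs plus a manifest.
See the vignette (`vignettes/history-bias-adaptation.Rmd`) for the models,
conventions and design decisions.

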