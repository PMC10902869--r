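Package: histbias
Title: Choice History Biases and Their Adaptation to Sequential Regularities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of choice history biases in
    two-alternative forced-choice (2AFC) orientation discrimination.
    Generates counterbalanced and Markov trial sequences with manipulated
    stimulus repetition probability, renders grating-in-noise stimuli and
    their Gabor filter-bank orientation-energy profiles, simulates
    psychometric observers with lagged stimulus/choice history kernels and
    prediction-dependent sensitivity gains, fits lasso-regularized logistic
    history-bias models with lapse rates, and implements an orientation-energy
    reverse-correlation pipeline that dissociates stimulus-independent
    decision bias from stimulus-dependent sensitivity. Includes parameter
    recovery simulations, exclusion-rule filters, and the group-level
    contrasts (paired t tests, within-subject ANOVA, rank correlations,
    linear trajectory fits) used to summarize history-bias adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
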