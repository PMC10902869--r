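make_behavior <- function(obs, seed, blocks = 6L) {
  des <- build_session(session_config(n_blocks_per_env = blocks), seed = seed)
  simulate_session(obs, des, seed = seed + 1L)
}

test_that("the design matrix implements the lag and exclusion rules", {
  obs <- observer_params()
  b <- make_behavior(obs, seed = 61)
  dm <- build_design_matrix(b, "neutral", n_lags = 7)
  expect_equal(nrow(dm$X), 593L)
  expect_equal(sum(grepl("^[sr]\\d", colnames(dm$X))), 14L)
  expect_equal(colnames(dm$X)[1], "stim")

  # row-by-row audit of the lag columns on a 20-trial fixture
  d20 <- b[b$environment == "repeating", ][1:20, ]
  dm20 <- suppressWarnings(build_design_matrix(d20, "repeating", n_lags = 7))
  for (i in seq_len(nrow(dm20$X))) {
    t <- i + 7L
    expect_equal(unname(dm20$X[i, "s1"]), d20$orientation[t - 1L])
    expect_equal(unname(dm20$X[i, "s3"]), d20$orientation[t - 3L])
    expect_equal(unname(dm20$X[i, "r2"]), d20$response[t - 2L])
    expect_equal(unname(dm20$X[i, "stim"]),
                 d20$orientation[t] * d20$contrast[t])
  }

  # lags never cross the environment boundary: neutral rows of the full
  # session never see repeating trials, and vice versa
  dmr <- build_design_matrix(b, "repeating", n_lags = 7)
  expect_equal(nrow(dmr$X), 593L)

  # a missing response drops the row but lag positions keep a 0 choice code
  bm <- b[b$environment == "neutral", ]
  bm$response[100] <- NA
  bm$is_correct[100] <- NA
  dmm <- build_design_matrix(bm, "neutral", n_lags = 7)
  expect_equal(nrow(dmm$X), 592L)
  row101 <- which(seq.int(8L, 600L)[!is.na(bm$response[8:600])] == 101L)
  expect_equal(unname(dmm$X[row101, "r1"]), 0)

  expect_warning(build_design_matrix(b[b$environment == "neutral", ][1:40, ],
                                     "neutral"), "analyzable")
})

long_neutral_design <- function(n, seed) {
  s <- generate_counterbalanced_sequence(n, seed = seed)
  s <- assign_correct_labels(s, seed = seed + 1L)
  data.frame(environment = "neutral", block = 1L, trial = seq_len(n),
             orientation = s$orientation, contrast = s$contrast,
             correct_label = s$correct_label)
}

test_that("null-observer fits recover zero history weights", {
  obs <- observer_params(w_stim = rep(0, 7), w_choice = rep(0, 7),
                         lapse_cw = 0, lapse_ccw = 0)
  des <- long_neutral_design(1e4, seed = 101)
  b <- simulate_session(obs, des, seed = 3)
  fit <- fit_history_model(build_design_matrix(b, "neutral"),
                           lapse_grid = 0)
  hist_w <- fit$weights[grepl("^[sr]\\d", names(fit$weights))]
  expect_lt(max(abs(hist_w)), 0.05)
  expect_true(fit$converged)
})

test_that("a planted lag-1 stimulus kernel is recovered within 0.1", {
  obs <- observer_params(w_stim = c(0.4, rep(0, 6)),
                         w_choice = rep(0, 7), lapse_cw = 0.02,
                         lapse_ccw = 0.02)
  des <- long_neutral_design(1e4, seed = 401)
  b <- simulate_session(obs, des, seed = 5)
  fit <- fit_history_model(build_design_matrix(b, "neutral"))
  expect_lt(abs(fit$weights["s1"] - 0.4), 0.1)
})

test_that("the lasso path shrinks to zero and relaxes to the MLE", {
  obs <- observer_params()
  b <- make_behavior(obs, seed = 71)
  dm <- build_design_matrix(b, "neutral")
  # huge penalty: all history weights exactly zero
  f_big <- fit_history_model(dm, lambda = 10, lapse_grid = 0)
  expect_true(all(f_big$weights[grepl("^[sr]\\d", names(f_big$weights))] == 0))
  # vanishing penalty: matches the unpenalized logistic MLE
  f_0 <- fit_history_model(dm, lambda = 0, lapse_grid = 0)
  g <- stats::glm(dm$y ~ dm$X, family = stats::binomial())
  expect_equal(unname(f_0$weights), unname(stats::coef(g)), tolerance = 1e-5)
})

test_that("the penalized fit agrees with glmnet at fixed zero lapses", {
  skip_if_not_installed("glmnet")
  obs <- observer_params()
  b <- make_behavior(obs, seed = 81)
  dm <- build_design_matrix(b, "repeating")
  fit <- fit_history_model(dm, lambda = 0.001, lapse_grid = 0)
  # glmnet rescales penalty.factor to sum to nvars: undo that in lambda
  g <- glmnet::glmnet(dm$X, dm$y, family = "binomial",
                      lambda = 0.001 * 14 / 15,
                      penalty.factor = c(0, rep(1, 14)),
                      standardize = FALSE, thresh = 1e-14)
  ref <- c(as.numeric(g$a0), as.numeric(g$beta))
  expect_equal(unname(fit$weights), ref, tolerance = 1e-5)
})

test_that("previous-correct weights equal an explicit reparameterized refit", {
  obs <- observer_params()
  b <- make_behavior(obs, seed = 91)
  dm <- build_design_matrix(b, "neutral")
  fit <- fit_history_model(dm, lambda = 0, lapse_grid = 0)
  # refit with previous-correct / previous-incorrect coded columns
  dm2 <- dm
  for (k in 1:7) {
    s <- dm$X[, paste0("s", k)]
    r <- dm$X[, paste0("r", k)]
    dm2$X[, paste0("s", k)] <- ifelse(r == s, r, 0)    # prev correct
    dm2$X[, paste0("r", k)] <- ifelse(r == -s, r, 0)   # prev incorrect
  }
  fit2 <- fit_history_model(dm2, lambda = 0, lapse_grid = 0)
  for (k in 1:7) {
    expect_equal(unname(fit2$weights[paste0("s", k)]),
                 unname(fit$weights[paste0("s", k)] +
                          fit$weights[paste0("r", k)]), tolerance = 1e-4)
    expect_equal(unname(fit2$weights[paste0("r", k)]),
                 unname(fit$weights[paste0("r", k)] -
                          fit$weights[paste0("s", k)]), tolerance = 1e-4)
  }
})

test_that("history summaries apply the defining linear maps", {
  f <- structure(list(weights = c(intercept = 0, stim = 5,
                                  stats::setNames(c(0.3, rep(0.01, 6)), paste0("s", 1:7)),
                                  stats::setNames(c(0.2, rep(-0.01, 6)), paste0("r", 1:7))),
                      converged = TRUE, n_lags = 7L), class = "history_fit")
  s <- derive_history_summaries(f, f)
  expect_equal(s$prev_correct_neutral[1], 0.5)
  expect_equal(s$prev_incorrect_neutral[1], -0.1)
  expect_true(all(s$adaptation == 0))
})

test_that("accuracy summaries respect chance, oracle, and low-contrast rules", {
  null_obs <- observer_params(w_stim = rep(0, 7), w_choice = rep(0, 7),
                              slope = 0, lapse_cw = 0, lapse_ccw = 0)
  des <- build_session(session_config(n_blocks_per_env = 9L), seed = 14)
  b <- simulate_session(null_obs, des, seed = 15)
  acc <- accuracy_summaries(b)
  zero_neutral <- b$contrast == 0 & b$environment == "neutral"
  expect_equal(mean(b$is_correct[zero_neutral]), 0.5, tolerance = 0.05)
  expect_equal(sort(unique(acc$by_block$block)), 1:18)

  oracle <- b
  oracle$response <- oracle$correct_label
  oracle$is_correct <- TRUE
  acc_o <- accuracy_summaries(oracle)
  expect_true(all(acc_o$by_contrast_env$accuracy == 1))

  # low contrast means contrasts strictly below 0.06
  lc <- acc$low_contrast
  n_low <- sum(b$contrast %in% c(0, 0.02, 0.04))
  expect_equal(sum(lc$n), n_low)
})

test_that("an adapted observer beats chance on repeating 0%-contrast trials", {
  adapted <- observer_params(w_stim = history_kernel(0.5),
                             w_choice = history_kernel(0.3))
  des <- build_session(session_config(n_blocks_per_env = 9L), seed = 24)
  b <- simulate_session(adapted, des, seed = 25)
  zero_rep <- b$contrast == 0 & b$environment == "repeating"
  expect_gt(mean(b$is_correct[zero_rep]), 0.5)
})

test_that("conditioned psychometric curves separate only for history observers", {
  sep_at_zero <- function(b) {
    pp <- conditioned_psychometric(b)
    z <- pp[pp$signed_contrast == 0, ]
    t(vapply(split(z, z$environment), function(d)
      c(sep = d$p_cw[d$prev_stim > 0] - d$p_cw[d$prev_stim < 0],
        se = sqrt(0.25 / d$n[d$prev_stim > 0] + 0.25 / d$n[d$prev_stim < 0])),
      numeric(2)))
  }
  null_obs <- observer_params(w_stim = rep(0, 7), w_choice = rep(0, 7),
                              lapse_cw = 0, lapse_ccw = 0)
  des <- build_session(session_config(n_blocks_per_env = 9L), seed = 34)
  s_null <- sep_at_zero(simulate_session(null_obs, des, seed = 35))
  # no separation beyond binomial error for a history-free observer
  expect_lt(max(abs(s_null[, "sep"]) / s_null[, "se"]), 3)

  adapted <- observer_params(w_stim = history_kernel(0.8),
                             w_choice = history_kernel(0.3))
  s_hist <- sep_at_zero(simulate_session(adapted, des, seed = 36))
  expect_gt(min(s_hist[, "sep"]), 0.1)

  # model-predicted curves are monotone for a positive-slope observer
  b <- simulate_session(adapted, des, seed = 37)
  fits <- list(neutral = fit_history_model(build_design_matrix(b, "neutral"),
                                           lapse_grid = 0))
  pp <- conditioned_psychometric(b, fits = fits)
  curve <- pp[pp$environment == "neutral" & pp$prev_stim > 0, ]
  expect_true(all(diff(curve$p_cw_model[order(curve$signed_contrast)]) > 0))
})

test_that("exclusion criteria flag the rule that fired", {
  obs <- observer_params(slope = 30, lapse_cw = 0, lapse_ccw = 0,
                         w_stim = rep(0, 7), w_choice = rep(0, 7))
  des <- build_session(seed = 44)
  good <- simulate_session(obs, des, seed = 45, participant_id = "good")

  # rule 2: 61 missed responses out of 1200
  missed <- simulate_session(obs, des, seed = 46, participant_id = "missed")
  missed$response[1:61] <- NA
  missed$is_correct[1:61] <- NA

  # rule 3: below 65% in one environment only
  lapsy <- simulate_session(obs, des, seed = 47, participant_id = "lapsy")
  rep_rows <- which(lapsy$environment == "repeating")
  set.seed(1)
  flip <- sample(rep_rows, 350)
  lapsy$response[flip] <- -lapsy$correct_label[flip]
  lapsy$is_correct[flip] <- FALSE

  res <- apply_exclusion_criteria(rbind(good, missed, lapsy))
  rep_tab <- res$report[match(c("good", "missed", "lapsy"),
                              res$report$participant_id), ]
  expect_equal(rep_tab$excluded, c(FALSE, TRUE, TRUE))
  expect_equal(rep_tab$rules_fired[2], "2")
  expect_true(grepl("3", rep_tab$rules_fired[3]))
  expect_equal(unique(res$data$participant_id), "good")
})
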