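test_that("z-scoring standardizes every group and cell exactly", {
  set.seed(1)
  E <- matrix(rexp(40 * 6), 40, 6)
  groups <- data.frame(participant = "p1",
                       prev_stim = rep(c(-1, 1), each = 20),
                       environment = "repeating")
  z <- zscore_energy(E, groups)
  for (g in c(-1, 1)) {
    rows <- groups$prev_stim == g
    expect_lt(max(abs(colMeans(z[rows, ]))), 1e-10)
    expect_lt(max(abs(apply(z[rows, ], 2, sd) - 1)), 1e-10)
  }
  expect_equal(nrow(attr(z, "dropped")), 0L)

  # hand-computed 5-value group with the sample-SD convention
  x <- c(2, 4, 4, 7, 13)
  zh <- zscore_energy(cbind(x), data.frame(g = rep(1, 5)))
  expect_equal(as.numeric(zh), (x - 6) / sqrt(sum((x - 6)^2) / 4))

  # constant cells are dropped and logged
  E2 <- cbind(E[, 1], 3)
  z2 <- zscore_energy(E2, groups)
  expect_true(all(is.na(z2[, 2])))
  expect_equal(nrow(attr(z2, "dropped")), 2L)

  expect_error(zscore_energy(E[1:2, ], groups[1:2, ][c(1, 1), ]),
               NA) # 2 per group is the minimum
  expect_error(zscore_energy(E[1, , drop = FALSE], groups[1, , drop = FALSE]),
               "at least 2")
})

test_that("per-bin logistic fits recover planted coefficients", {
  set.seed(7)
  n <- 1e4
  z <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.5 + 0 * z))
  f <- fit_bin(z, y)
  expect_lt(abs(f$beta0 - 0.5), 0.07)
  expect_lt(abs(f$beta1), 0.07)
  expect_false(f$separated)

  # balanced energy-independent responses: both coefficients near zero
  y0 <- rep(c(0, 1), n / 2)
  f0 <- fit_bin(z, y0)
  expect_lt(abs(f0$beta0), 0.07)
  expect_lt(abs(f0$beta1), 0.07)

  # perfectly label-matched energies: separation flag
  ys <- as.numeric(z > 0)
  fs <- fit_bin(z, ys)
  expect_true(fs$separated)
  expect_lte(abs(fs$beta1), 10)

  expect_error(fit_bin(z, rep(1, n)), "both response classes")
})

test_that("batched cell fits equal stats::glm cell by cell", {
  set.seed(11)
  n <- 300
  Z <- matrix(rnorm(n * 25), n)
  y <- rbinom(n, 1, plogis(0.3 + 0.6 * Z[, 3] - 0.4 * Z[, 17]))
  fb <- histbias:::fit_bins_batch(Z, y)
  for (j in c(1, 3, 12, 17, 25)) {
    g <- stats::glm(y ~ Z[, j], family = stats::binomial())
    expect_equal(fb$beta0[j], unname(coef(g)[1]), tolerance = 1e-8)
    expect_equal(fb$beta1[j], unname(coef(g)[2]), tolerance = 1e-8)
    expect_false(fb$separated[j])
  }
  # NA (dropped) cells propagate
  Zna <- Z
  Zna[, 5] <- NA
  fna <- histbias:::fit_bins_batch(Zna, y)
  expect_true(is.na(fna$beta0[5]))
})

test_that("Tukey-fence filtering matches a brute-force quartile oracle", {
  v <- c(1:10, 100)
  keep <- remove_outliers_iqr(v)
  expect_equal(which(!keep), 11L)
  # brute-force linear-interpolation quartiles
  srt <- sort(v)
  q1 <- srt[3] + 0.5 * (srt[4] - srt[3])
  q3 <- srt[8] + 0.5 * (srt[9] - srt[8])
  expect_equal(unname(attr(keep, "fences")),
               c(q1 - 1.5 * (q3 - q1), q3 + 1.5 * (q3 - q1)))

  # identical values: zero IQR keeps everything inside closed fences
  expect_true(all(remove_outliers_iqr(rep(2.5, 8))))

  # Gaussian samples lose about 0.7% in total (Tukey expectation)
  set.seed(3)
  x <- rnorm(1e4)
  frac <- mean(!remove_outliers_iqr(x))
  expect_gt(frac, 0.003)
  expect_lt(frac, 0.012)

  expect_warning(remove_outliers_iqr(c(1, 2, 3)), "too small")
})

test_that("summaries compute bias, class sensitivities and the history effect", {
  # constructed bin-fit table with known cell values
  cells <- expand.grid(orientation_deg = c(-60, -45, -30, 0, 30, 45, 60, 90),
                       sf_cpd = 1)
  grid <- expand.grid(prev_stim = c(-1, 1),
                      environment = c("neutral", "repeating"),
                      stringsAsFactors = FALSE)
  fits <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cw <- cells$orientation_deg %in% c(30, 45, 60)
    b1 <- ifelse(cw,
                 ifelse(g$environment == "repeating" & g$prev_stim == 1,
                        0.9, 0.4),
                 0.2)
    data.frame(participant = "p1", environment = g$environment,
               prev_stim = g$prev_stim,
               orientation_deg = cells$orientation_deg,
               sf_cpd = cells$sf_cpd,
               beta0 = 0.1 * g$prev_stim, beta1 = b1, separated = FALSE)
  }))
  s <- suppressWarnings(summarize_revcorr(fits))
  # bias averages all cells; split by previous stimulus
  expect_equal(s$bias$bias[s$bias$prev_stim == 1], c(0.1, 0.1))
  expect_equal(s$bias$bias[s$bias$prev_stim == -1], c(-0.1, -0.1))
  # 0 and 90 degrees excluded from the orientation classes
  cw_n <- s$sensitivity$sensitivity[s$sensitivity$energy_class == "cw" &
                                      s$sensitivity$environment == "neutral"]
  expect_equal(unique(cw_n), 0.4)
  eff <- s$history_effect
  expect_equal(eff$history_sensitivity_effect[eff$environment == "repeating"],
               0.9 - 0.4)
  expect_equal(eff$history_sensitivity_effect[eff$environment == "neutral"], 0)
})

test_that("the pipeline only accepts 0%-contrast energies", {
  des <- zero_contrast_design(60, seed = 2)
  des$contrast[5] <- 0.12
  bank <- fixture_bank(64)
  en <- design_energies(des, bank, seed = 3)
  obs <- observer_params()
  b <- simulate_session(obs, des, seed = 4)
  expect_error(fit_revcorr_bins(b, en$energy, des$trial, cells = bank$cells),
               "0%-contrast")
})

test_that("label flipping negates biases and swaps the sensitivity classes", {
  bank <- fixture_bank(64)
  des <- zero_contrast_design(240, seed = 21)
  en <- design_energies(des, bank, seed = 22)
  obs <- observer_params(intercept = 0.3, w_stim = history_kernel(0.5),
                         w_choice = history_kernel(0.2), energy_beta = 1,
                         lapse_cw = 0, lapse_ccw = 0)
  b <- simulate_session(obs, des, energies = en$net, seed = 23)

  rc <- reverse_correlation(b, en$energy, des$trial, cells = bank$cells)

  # mirror the dataset: flip orientations, responses and labels, and
  # mirror the energy cells (orientation o -> -o; 90 maps to itself)
  bf <- b
  bf$orientation <- -bf$orientation
  bf$response <- -bf$response
  bf$correct_label <- -bf$correct_label
  ori <- bank$cells$orientation_deg
  flip_ori <- ifelse(-ori < -89, -ori + 180, -ori) # 90 -> 90
  perm <- match(interaction(flip_ori, bank$cells$sf_cpd),
                interaction(ori, bank$cells$sf_cpd))
  Ef <- en$energy[, perm]
  attr(Ef, "cells") <- bank$cells
  rcf <- reverse_correlation(bf, Ef, des$trial, cells = bank$cells)

  # fitting 1 - y on the mirrored cell of the swapped condition negates
  # both coefficients: beta_f(o, p) = -beta(-o, -p)
  keys <- function(env, prev, o, sf) paste(env, prev, o, sf)
  orig_key <- keys(rc$bins$environment, rc$bins$prev_stim,
                   rc$bins$orientation_deg, rc$bins$sf_cpd)
  mirror_o <- ifelse(-rcf$bins$orientation_deg < -89,
                     -rcf$bins$orientation_deg + 180,
                     -rcf$bins$orientation_deg)
  at <- match(keys(rcf$bins$environment, -rcf$bins$prev_stim, mirror_o,
                   rcf$bins$sf_cpd), orig_key)
  ok <- !rcf$bins$separated & !rc$bins$separated[at]
  expect_gt(mean(ok), 0.9)
  expect_equal(rcf$bins$beta0[ok], -rc$bins$beta0[at][ok], tolerance = 1e-7)
  expect_equal(rcf$bins$beta1[ok], -rc$bins$beta1[at][ok], tolerance = 1e-7)

  # summaries: bias negated with the previous stimulus swapped, and the
  # clockwise/counterclockwise sensitivity classes exchanged
  b_o <- rc$bias
  b_f <- rcf$bias
  at_b <- match(paste(b_f$environment, -b_f$prev_stim),
                paste(b_o$environment, b_o$prev_stim))
  expect_equal(b_f$bias, -b_o$bias[at_b], tolerance = 0.05)
})
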