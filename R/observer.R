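#' Generative parameters of a simulated 2AFC observer
#'
#' The observer responds clockwise with probability
#' `lapse_cw + (1 - lapse_cw - lapse_ccw) * logistic(eta)` where `eta` is the
#' sum of an intercept (overall clockwise bias), a slope on the signed
#' Michelson contrast, lagged stimulus and choice history kernels over the
#' previous seven trials (regressors coded +/-1, zero-padded at the start of
#' each environment), and -- on 0%-contrast trials -- a term driven by the
#' z-scored clockwise/counterclockwise orientation energy of the noise,
#' with multiplicative gains on the channel consistent vs. inconsistent with
#' the predicted orientation (the previous trial's stimulus orientation).
#'
#' @param intercept log-odds bias toward clockwise.
#' @param slope log-odds per unit signed Michelson contrast.
#' @param lapse_cw,lapse_ccw stimulus-independent clockwise /
#'   counterclockwise response rates; nonnegative, sum < 1.
#' @param w_stim,w_choice numeric length-7 history kernels (lag 1 first).
#' @param energy_beta log-odds per z-scored net orientation energy on
#'   0%-contrast trials.
#' @param gain_consistent,gain_inconsistent gains on the energy channel
#'   matching / opposing the predicted orientation.
#' @return an `observer_params` list.
#' @export
observer_params <- function(intercept = 0, slope = 15,
                            lapse_cw = 0.02, lapse_ccw = 0.02,
                            w_stim = history_kernel(0.25),
                            w_choice = history_kernel(0.15),
                            energy_beta = 0,
                            gain_consistent = 1, gain_inconsistent = 1) {
  stopifnot(length(w_stim) == 7L, length(w_choice) == 7L,
            is.numeric(w_stim), is.numeric(w_choice))
  if (lapse_cw < 0 || lapse_ccw < 0 || lapse_cw + lapse_ccw >= 1) {
    stop("lapse rates must be nonnegative with lapse_cw + lapse_ccw < 1",
         call. = FALSE)
  }
  structure(list(intercept = intercept, slope = slope,
                 lapse_cw = lapse_cw, lapse_ccw = lapse_ccw,
                 w_stim = w_stim, w_choice = w_choice,
                 energy_beta = energy_beta,
                 gain_consistent = gain_consistent,
                 gain_inconsistent = gain_inconsistent),
            class = "observer_params")
}

#' Geometrically decaying 7-lag history kernel
#'
#' @param amplitude lag-1 weight.
#' @param decay per-lag decay factor.
#' @return numeric vector of length 7.
#' @export
history_kernel <- function(amplitude, decay = 0.5) {
  amplitude * decay^(0:6)
}

#' Simulate one session of a generative observer
#'
#' @param params an [observer_params()] list.
#' @param design a [build_session()] design (or any data.frame with
#'   `environment`, `block`, `trial`, `orientation`, `contrast`,
#'   `correct_label`).
#' @param energies optional data.frame with columns `trial`, `e_cw`, `e_ccw`
#'   (raw class-mean orientation energies, see [class_net_energies()]) for
#'   the design's 0%-contrast trials; required when `energy_beta != 0` or
#'   the gains differ from 1 and the design contains 0%-contrast trials.
#'   Energies are z-scored per environment and channel before use.
#' @param seed integer seed.
#' @param participant_id participant label for the output.
#' @return a `behavioral_dataset` data.frame: per-trial records with
#'   `signed_contrast`, `response` (+/-1) and `is_correct` added.
#' @export
simulate_session <- function(params, design, energies = NULL, seed = 1L,
                             participant_id = "sim01") {
  stopifnot(inherits(params, "observer_params"), is.data.frame(design))
  n <- nrow(design)
  uses_energy <- params$energy_beta != 0 ||
    params$gain_consistent != 1 || params$gain_inconsistent != 1
  has_zero <- any(design$contrast == 0)
  if (uses_energy && has_zero && is.null(energies)) {
    stop(paste("orientation energies must be supplied for 0%-contrast trials",
               "when energy_beta != 0 or gains differ from 1"), call. = FALSE)
  }

  signed_contrast <- design$orientation * design$contrast
  env <- design$environment
  env_start <- !duplicated(env) # TRUE at the first trial of each environment

  # z-scored class energies per environment, aligned to design rows
  zcw <- zccw <- rep(NA_real_, n)
  if (!is.null(energies) && has_zero) {
    stopifnot(all(c("trial", "e_cw", "e_ccw") %in% names(energies)))
    pos <- match(energies$trial, design$trial)
    stopifnot(!anyNA(pos))
    for (e in unique(env)) {
      g <- env[pos] == e
      if (sum(g) >= 2L) {
        zcw[pos[g]] <- as.numeric(scale(energies$e_cw[g]))
        zccw[pos[g]] <- as.numeric(scale(energies$e_ccw[g]))
      }
    }
  }

  # stimulus-kernel contribution is response-independent: vectorize it
  stim_drive <- numeric(n)
  for (k in 1:7) {
    lag_ori <- c(rep(0, k), design$orientation[seq_len(n - k)])
    same_env <- c(rep(FALSE, k),
                  env[seq_len(n - k)] == env[(k + 1):n])
    stim_drive <- stim_drive + params$w_stim[k] * lag_ori * same_env
  }

  set.seed(seed)
  u <- stats::runif(n)
  response <- numeric(n)
  r_hist <- numeric(7) # lag 1 first, reset at environment switch
  prev_ori <- NA_real_
  for (t in seq_len(n)) {
    if (env_start[t]) {
      r_hist[] <- 0
      prev_ori <- NA_real_
    }
    eta <- params$intercept + params$slope * signed_contrast[t] +
      stim_drive[t] + sum(params$w_choice * r_hist)
    if (design$contrast[t] == 0 && !is.na(prev_ori) && !is.na(zcw[t])) {
      g_cw <- if (prev_ori > 0) params$gain_consistent else params$gain_inconsistent
      g_ccw <- if (prev_ori < 0) params$gain_consistent else params$gain_inconsistent
      eta <- eta + params$energy_beta * (g_cw * zcw[t] - g_ccw * zccw[t])
    }
    p_cw <- params$lapse_cw +
      (1 - params$lapse_cw - params$lapse_ccw) * stats::plogis(eta)
    response[t] <- if (u[t] < p_cw) 1 else -1
    r_hist <- c(response[t], r_hist[1:6])
    prev_ori <- design$orientation[t]
  }

  out <- data.frame(participant_id = participant_id,
                    environment = env,
                    block = design$block,
                    trial = design$trial,
                    orientation = design$orientation,
                    contrast = design$contrast,
                    signed_contrast = signed_contrast,
                    correct_label = design$correct_label,
                    response = response,
                    is_correct = response == design$correct_label)
  class(out) <- c("behavioral_dataset", "data.frame")
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

#' Parameter-recovery simulation for the history-bias model
#'
#' Simulates `n_sims` response sets of an observer with known parameters on a
#' repeating-environment stimulus sequence and refits the lasso-regularized
#' history model to each, to verify that history weights are recoverable
#' despite the stimulus autocorrelation of the repeating environment.
#'
#' @param params generating [observer_params()] (energy terms must be inert:
#'   recovery uses no stimulus rendering).
#' @param design a repeating-environment design (a [build_session()] result
#'   restricted to one environment also works).
#' @param n_sims number of simulated response sets.
#' @param seed integer seed.
#' @param lambda lasso penalty passed to [fit_history_model()].
#' @param n_lags number of history lags.
#' @param lapse_grid lapse-rate search passed to [fit_history_model()];
#'   defaults to the fitter's default.
#' @return a `recovery_result` list: `weights` (n_sims x regressors matrix),
#'   `mean`, `generating` (named generating values), `bias`
#'   (mean refit minus generating value per regressor), and `failed`
#'   (indices of non-converged fits).
#' @export
recovery_simulation <- function(params, design, n_sims = 100L, seed = 1L,
                                lambda = 0.001, n_lags = 7L,
                                lapse_grid = NULL) {
  stopifnot(inherits(params, "observer_params"), n_sims >= 1L)
  env <- unique(design$environment)
  stopifnot(length(env) == 1L)
  fits <- vector("list", n_sims)
  failed <- integer(0)
  for (s in seq_len(n_sims)) {
    dat <- simulate_session(params, design, seed = derive_seed(seed, paste0("recovery:", s)))
    dm <- build_design_matrix(dat, env = env, n_lags = n_lags)
    fit <- tryCatch(fit_history_model(dm, lambda = lambda,
                                      lapse_grid = lapse_grid),
                    error = function(e) {
                      stop(sprintf("fit failed in simulation %d: %s",
                                   s, conditionMessage(e)), call. = FALSE)
                    })
    if (!fit$converged) failed <- c(failed, s)
    fits[[s]] <- fit$weights
  }
  w <- do.call(rbind, fits)
  gen <- c(intercept = params$intercept, stim = params$slope,
           stats::setNames(params$w_stim, paste0("s", 1:7))[seq_len(n_lags)],
           stats::setNames(params$w_choice, paste0("r", 1:7))[seq_len(n_lags)])
  gen <- gen[colnames(w)]
  structure(list(weights = w, mean = colMeans(w), generating = gen,
                 bias = colMeans(w) - gen, failed = failed,
                 n_sims = n_sims),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("history-weight recovery over %d simulations (%d non-converged)\n",
              x$n_sims, length(x$failed)))
  print(round(rbind(generating = x$generating, recovered = x$mean,
                    bias = x$bias), 3))
  invisible(x)
}
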