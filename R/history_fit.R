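#' Build the lagged history design matrix for one environment
#'
#' Rows are the analyzable trials of one environment: the first `n_lags`
#' trials are excluded (lags never cross the environment boundary), as are
#' trials with a missing response. Columns are the current signed contrast
#' and the stimulus (`s1..s7`) and choice (`r1..r7`) signs of the previous
#' `n_lags` trials; the intercept and the lapse rates are handled inside the
#' fitter. Missed responses occupy their lag positions with a 0 choice
#' regressor.
#'
#' @param data a `behavioral_dataset` (single participant).
#' @param env `"neutral"` or `"repeating"`.
#' @param n_lags number of history lags (default 7).
#' @return a `history_design_matrix` list: `X` (rows x `1 + 2 n_lags`
#'   columns), `y` (clockwise indicator), `penalized` (logical per column:
#'   TRUE for the history columns), `env`, `n_source`. A `low_n` attribute
#'   flags fewer than 50 analyzable rows.
#' @export
build_design_matrix <- function(data, env, n_lags = 7L) {
  stopifnot(is.data.frame(data), env %in% data$environment, n_lags >= 1L)
  d <- data[data$environment == env, , drop = FALSE]
  d <- d[order(d$trial), , drop = FALSE]
  n <- nrow(d)
  if (n <= n_lags) stop("not enough trials for the requested lags", call. = FALSE)
  resp <- ifelse(is.na(d$response), 0, d$response)
  keep <- seq.int(n_lags + 1L, n)
  X <- matrix(0, length(keep), 1L + 2L * n_lags)
  colnames(X) <- c("stim", paste0("s", seq_len(n_lags)),
                   paste0("r", seq_len(n_lags)))
  X[, "stim"] <- d$orientation[keep] * d$contrast[keep]
  for (k in seq_len(n_lags)) {
    X[, paste0("s", k)] <- d$orientation[keep - k]
    X[, paste0("r", k)] <- resp[keep - k]
  }
  ok <- !is.na(d$response[keep])
  X <- X[ok, , drop = FALSE]
  y <- as.numeric(d$response[keep][ok] == 1)
  out <- list(X = X, y = y, env = env,
              penalized = c(FALSE, rep(TRUE, 2L * n_lags)),
              n_source = n, n_lags = n_lags)
  class(out) <- "history_design_matrix"
  if (nrow(X) < 50L) {
    attr(out, "low_n") <- TRUE
    warning(sprintf("only %d analyzable trials in %s environment",
                    nrow(X), env), call. = FALSE)
  }
  out
}

# internal: penalized negative log-likelihood (per observation) of the
# lapse-augmented logistic model; penalty on the flagged columns only
pnll <- function(beta, X1, y, pen, lambda, gcw, gccw) {
  a <- 1 - gcw - gccw
  p <- gcw + a * stats::plogis(X1 %*% beta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p)) + lambda * sum(abs(beta[pen]))
}

# internal: one pass of cyclic coordinate descent for the penalized weighted
# least-squares problem (1/2n) sum_i w_i (z_i - X1 beta)^2 + sum_j pl_j |b_j|
cd_wls <- function(X1, z, w, pl, beta, n, max_sweeps = 100L, tol = 1e-10) {
  r <- z - drop(X1 %*% beta)
  wX <- X1 * w
  wx2 <- colSums(wX * X1) / n
  for (s in seq_len(max_sweeps)) {
    delta <- 0
    for (j in seq_along(beta)) {
      if (wx2[j] <= 1e-14) next
      rho <- sum(wX[, j] * r) / n + wx2[j] * beta[j]
      bn <- if (pl[j] > 0) {
        sign(rho) * max(abs(rho) - pl[j], 0) / wx2[j]
      } else {
        rho / wx2[j]
      }
      d <- bn - beta[j]
      if (d != 0) {
        r <- r - X1[, j] * d
        beta[j] <- bn
        delta <- max(delta, abs(d))
      }
    }
    if (delta < tol) break
  }
  beta
}

# internal: penalized Fisher-scoring (IRLS) solver for one fixed lapse pair.
# The lapse-augmented response probability p = gcw + (1 - gcw - gccw) *
# logistic(eta) is a binomial GLM with a non-canonical inverse link, so each
# step solves a weighted lasso least-squares problem by coordinate descent,
# with step halving on the exact penalized objective.
irls_fit <- function(X1, y, pen, lambda, gcw, gccw, beta0,
                     tol = 1e-8, maxit = 10000L) {
  a <- 1 - gcw - gccw
  n <- length(y)
  pl <- ifelse(pen, lambda, 0)
  beta <- beta0
  f_old <- pnll(beta, X1, y, pen, lambda, gcw, gccw)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    p <- pmin(pmax(gcw + a * mu, 1e-12), 1 - 1e-12)
    dp <- pmax(a * mu * (1 - mu), 1e-10)
    w <- dp^2 / (p * (1 - p))
    z <- eta + (y - p) / dp
    prop <- cd_wls(X1, z, w, pl, beta, n)
    step <- 1
    accepted <- FALSE
    repeat {
      cand <- beta + step * (prop - beta)
      f_new <- pnll(cand, X1, y, pen, lambda, gcw, gccw)
      if (f_new <= f_old + 1e-14) {
        accepted <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-4) break
    }
    if (!accepted) { # no descent left: at a numerical optimum
      converged <- TRUE
      break
    }
    beta <- cand
    if (abs(f_old - f_new) <= tol * (abs(f_old) + 1e-12)) {
      converged <- TRUE
      f_old <- f_new
      break
    }
    f_old <- f_new
  }
  list(beta = beta, objective = f_old, converged = converged, iters = it)
}

#' Fit the lasso-regularized logistic history-bias model
#'
#' Minimizes the per-observation penalized negative log-likelihood of
#' `P(clockwise) = lapse_cw + (1 - lapse_cw - lapse_ccw) * logistic(X beta)`
#' with an L1 penalty `lambda` on the 14 history columns only (intercept,
#' current-stimulus slope and lapse rates unpenalized). Lapse rates are
#' selected by a bounded grid search on `[0, 0.2]` at 0.01 resolution,
#' performed coarse-to-fine with warm starts; pass an explicit numeric
#' `lapse_grid` for a flat grid, or `0` to fix lapses at zero.
#'
#' @param dm a [build_design_matrix()] result.
#' @param lambda lasso penalty (default 0.001, applied per observation to the
#'   +/-1-coded history columns).
#' @param lapse_grid `NULL` (default coarse-to-fine search at 0.01
#'   resolution) or a numeric vector of candidate lapse rates used for both
#'   lapse parameters.
#' @param tol relative objective tolerance of the inner solver.
#' @param maxit maximum inner iterations.
#' @return a `history_fit`: `weights` (named: `intercept`, `stim`,
#'   `s1..s7`, `r1..r7`), `lapse_cw`, `lapse_ccw`, `lambda`, `env`,
#'   `converged`, `objective`, `n`, and fit metadata.
#' @export
fit_history_model <- function(dm, lambda = 0.001, lapse_grid = NULL,
                              tol = 1e-8, maxit = 10000L) {
  stopifnot(inherits(dm, "history_design_matrix"))
  y <- dm$y
  degenerate <- length(unique(y)) < 2L
  X1 <- cbind(intercept = 1, dm$X)
  pen <- c(FALSE, dm$penalized)
  beta0 <- numeric(ncol(X1))

  run_one <- function(gcw, gccw, warm, iters = maxit) {
    irls_fit(X1, y, pen, lambda, gcw, gccw, warm, tol = tol, maxit = iters)
  }

  # scan with a capped iteration budget (objective ranking is stable well
  # before full convergence); the selected lapse pair is re-solved in full
  search <- function(values, warm) {
    best <- NULL
    for (gcw in values$cw) {
      for (gccw in values$ccw) {
        if (gcw + gccw >= 1) next
        fit <- irls_fit(X1, y, pen, lambda, gcw, gccw, warm,
                        tol = max(tol, 1e-6), maxit = min(maxit, 40L))
        warm <- fit$beta
        if (is.null(best) || fit$objective < best$objective) {
          best <- c(fit, list(lapse_cw = gcw, lapse_ccw = gccw))
        }
      }
    }
    best
  }

  if (degenerate) {
    # one response class only: the likelihood has no finite optimum; return
    # a capped, flagged fit rather than searching the lapse grid
    one <- irls_fit(X1, y, pen, lambda, 0, 0, beta0, tol = tol,
                    maxit = min(maxit, 50L))
    best <- c(one, list(lapse_cw = 0, lapse_ccw = 0))
  } else if (is.null(lapse_grid)) {
    coarse <- seq(0, 0.2, by = 0.04)
    best <- search(list(cw = coarse, ccw = coarse), beta0)
    fine_around <- function(g) {
      seq(max(0, g - 0.03), min(0.2, g + 0.03), by = 0.01)
    }
    best <- search(list(cw = fine_around(best$lapse_cw),
                        ccw = fine_around(best$lapse_ccw)), best$beta)
    polish <- run_one(best$lapse_cw, best$lapse_ccw, best$beta)
    best[names(polish)] <- polish
  } else {
    stopifnot(is.numeric(lapse_grid), all(lapse_grid >= 0), all(lapse_grid < 1))
    best <- search(list(cw = lapse_grid, ccw = lapse_grid), beta0)
    polish <- run_one(best$lapse_cw, best$lapse_ccw, best$beta)
    best[names(polish)] <- polish
  }

  w <- stats::setNames(as.numeric(best$beta), colnames(X1))
  # separation heuristic on the +/-1-coded columns and the intercept only:
  # the contrast slope lives on a different unit scale
  converged <- best$converged && !degenerate &&
    max(abs(w[names(w) != "stim"])) < 15
  structure(list(weights = w, lapse_cw = best$lapse_cw,
                 lapse_ccw = best$lapse_ccw, lambda = lambda,
                 env = dm$env, converged = converged,
                 objective = best$objective, n = length(y),
                 n_lags = dm$n_lags,
                 meta = list(penalty = "per-observation L1 on history columns",
                             columns = "raw (+/-1 history, contrast-unit stimulus)",
                             lapse_resolution = 0.01)),
            class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat(sprintf("history-bias fit (%s environment, n = %d, lambda = %g)%s\n",
              x$env, x$n, x$lambda,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat(sprintf("  lapses: cw %.2f, ccw %.2f\n", x$lapse_cw, x$lapse_ccw))
  print(round(x$weights, 3))
  invisible(x)
}

#' Previous-correct / previous-incorrect weights and their adaptation
#'
#' With +/-1-coded regressors, the sum of the lag-k previous-stimulus and
#' previous-choice weights equals the weight of a previous-correct-choice
#' regressor, and their difference (choice minus stimulus) the
#' previous-incorrect-choice weight. Adaptation is the repeating-environment
#' previous-correct weight minus the neutral one.
#'
#' @param fit_neutral,fit_repeating converged [fit_history_model()] results
#'   for the two environments.
#' @return a data.frame with one row per lag: `prev_correct_neutral`,
#'   `prev_correct_repeating`, `prev_incorrect_neutral`,
#'   `prev_incorrect_repeating`, `adaptation`.
#' @export
derive_history_summaries <- function(fit_neutral, fit_repeating) {
  stopifnot(inherits(fit_neutral, "history_fit"),
            inherits(fit_repeating, "history_fit"))
  if (!fit_neutral$converged || !fit_repeating$converged) {
    stop("history summaries require converged fits in both environments",
         call. = FALSE)
  }
  lags <- seq_len(fit_neutral$n_lags)
  pc <- function(f) f$weights[paste0("s", lags)] + f$weights[paste0("r", lags)]
  pi_ <- function(f) f$weights[paste0("r", lags)] - f$weights[paste0("s", lags)]
  data.frame(lag = lags,
             prev_correct_neutral = unname(pc(fit_neutral)),
             prev_correct_repeating = unname(pc(fit_repeating)),
             prev_incorrect_neutral = unname(pi_(fit_neutral)),
             prev_incorrect_repeating = unname(pi_(fit_repeating)),
             adaptation = unname(pc(fit_repeating) - pc(fit_neutral)))
}
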