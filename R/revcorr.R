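#' Z-score orientation energies within condition groups
#'
#' Each energy cell (orientation x spatial frequency column) is z-scored
#' within every grouping-key combination (typically participant x previous
#' stimulus x environment), using the sample (n - 1) standard deviation.
#' Zero-variance cells within a group cannot be standardized and are set to
#' `NA` (dropped for that group) and logged.
#'
#' @param energy trials x cells matrix (see [compute_energy_profiles()]).
#' @param groups data.frame of grouping keys, one row per trial.
#' @return the z-scored matrix with a `dropped` attribute (data.frame of
#'   group/cell pairs that were dropped; zero rows when none).
#' @export
zscore_energy <- function(energy, groups) {
  stopifnot(is.matrix(energy), is.data.frame(groups),
            nrow(groups) == nrow(energy))
  key <- interaction(groups, drop = TRUE)
  if (any(table(key) < 2L)) {
    stop("every group must contain at least 2 trials", call. = FALSE)
  }
  z <- energy
  dropped <- list()
  for (g in levels(key)) {
    rows <- which(key == g)
    mu <- colMeans(energy[rows, , drop = FALSE])
    sdv <- apply(energy[rows, , drop = FALSE], 2L, stats::sd)
    bad <- sdv == 0 | is.na(sdv)
    sdv[bad] <- 1
    z[rows, ] <- sweep(sweep(energy[rows, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    if (any(bad)) {
      z[rows, bad] <- NA_real_
      dropped[[g]] <- data.frame(group = g, cell = which(bad))
    }
  }
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(group = character(0), cell = integer(0))
  rownames(dropped) <- NULL
  attr(z, "dropped") <- dropped
  attr(z, "cells") <- attr(energy, "cells")
  z
}

#' Logistic fit of responses on one cell's z-scored energy
#'
#' Maximum-likelihood fit of `P(clockwise) = logistic(beta0 + beta1 * z)`.
#' Complete or quasi-complete separation is flagged and the estimates are
#' truncated at `|beta| = 10` (flagged fits are excluded from downstream
#' summaries).
#'
#' @param z_energy numeric vector of z-scored energies.
#' @param responses clockwise indicators (0/1 or -1/+1).
#' @return a `revcorr_bin_fit` list: `beta0`, `beta1`, `separated`,
#'   `converged`.
#' @export
fit_bin <- function(z_energy, responses) {
  y <- as.numeric(responses > 0)
  stopifnot(length(y) == length(z_energy))
  if (length(unique(y)) < 2L) {
    stop("both response classes must be present", call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm(y ~ z_energy,
                                     family = stats::binomial()))
  b <- unname(stats::coef(fit))
  separated <- !fit$converged || any(abs(b) > 10) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  structure(list(beta0 = max(min(b[1L], 10), -10),
                 beta1 = max(min(b[2L], 10), -10),
                 separated = separated, converged = fit$converged),
            class = "revcorr_bin_fit")
}

# internal: vectorized Newton (IRLS) logistic fits across all cells at once;
# columns of Z with NA (dropped cells) yield NA estimates. Matches
# stats::glm to numerical precision on non-separated cells (tested).
fit_bins_batch <- function(Z, y, maxit = 60L, tol = 1e-10) {
  y <- as.numeric(y > 0)
  n <- nrow(Z)
  ok <- colSums(is.na(Z)) == 0L
  b0 <- rep(NA_real_, ncol(Z))
  b1 <- rep(NA_real_, ncol(Z))
  conv <- rep(FALSE, ncol(Z))
  if (any(ok) && length(unique(y)) == 2L) {
    Zo <- Z[, ok, drop = FALSE]
    c0 <- rep(stats::qlogis(mean(y)), ncol(Zo))
    c1 <- rep(0, ncol(Zo))
    active <- rep(TRUE, ncol(Zo))
    for (it in seq_len(maxit)) {
      eta <- sweep(sweep(Zo, 2L, c1, "*"), 2L, c0, "+")
      mu <- stats::plogis(eta)
      w <- mu * (1 - mu)
      r <- y - mu
      sw <- colSums(w); swz <- colSums(w * Zo); swzz <- colSums(w * Zo^2)
      sr <- colSums(r); srz <- colSums(r * Zo)
      det <- sw * swzz - swz^2
      det[det < 1e-12] <- NA
      d0 <- (swzz * sr - swz * srz) / det
      d1 <- (sw * srz - swz * sr) / det
      d0[is.na(d0)] <- 0
      d1[is.na(d1)] <- 0
      # dampen huge steps (separation drift)
      sc <- pmax(1, pmax(abs(d0), abs(d1)) / 5)
      c0 <- c0 + d0 / sc
      c1 <- c1 + d1 / sc
      moved <- pmax(abs(d0), abs(d1))
      active <- moved > tol
      if (!any(active)) break
    }
    conv_ok <- pmax(abs(d0), abs(d1)) <= 1e-6
    b0[ok] <- c0
    b1[ok] <- c1
    conv[ok] <- conv_ok
  }
  separated <- !conv | abs(b0) > 10 | abs(b1) > 10
  separated[is.na(b0)] <- NA
  list(beta0 = pmax(pmin(b0, 10), -10), beta1 = pmax(pmin(b1, 10), -10),
       separated = separated)
}

#' Tukey-fence outlier removal (1.5 x IQR rule)
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7); values
#' outside `[Q1 - factor * IQR, Q3 + factor * IQR]` are removed. Pools with
#' fewer than `min_n` values are returned unfiltered with a warning.
#'
#' @param values numeric vector (one pool).
#' @param factor fence multiplier (default 1.5).
#' @param min_n minimum pool size for filtering.
#' @return logical vector: `TRUE` for values kept; fences attached as the
#'   `"fences"` attribute.
#' @export
remove_outliers_iqr <- function(values, factor = 1.5, min_n = 4L) {
  stopifnot(is.numeric(values))
  if (sum(!is.na(values)) < min_n) {
    warning("pool too small for outlier filtering; returning all values",
            call. = FALSE)
    return(structure(rep(TRUE, length(values)), fences = c(-Inf, Inf)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7)
  iqr <- q[2L] - q[1L]
  fences <- c(q[1L] - factor * iqr, q[2L] + factor * iqr)
  keep <- !is.na(values) & values >= fences[1L] & values <= fences[2L]
  structure(keep, fences = fences)
}

#' Fit the reverse-correlation model for every cell and condition
#'
#' Restricted to 0%-contrast trials. Trials are conditioned on environment
#' and the previous stimulus orientation (within environment; the first
#' trial of each environment is dropped), energies are z-scored per
#' (participant, previous stimulus, environment) group and cell, and each
#' cell is fit with a logistic regression of the clockwise-response
#' indicator on the z-scored energy.
#'
#' @param data a `behavioral_dataset`; only rows with `contrast == 0` and a
#'   recorded response enter the fits.
#' @param energy trials x cells energy matrix for the 0%-contrast trials.
#' @param energy_trials trial ids (matching `data$trial`) for the rows of
#'   `energy`.
#' @param cells cell grid; defaults to the `"cells"` attribute of `energy`.
#' @return a data.frame of bin fits: participant, environment, prev_stim,
#'   orientation_deg, sf_cpd, beta0, beta1, separated.
#' @export
fit_revcorr_bins <- function(data, energy, energy_trials,
                             cells = attr(energy, "cells")) {
  stopifnot(!is.null(cells), nrow(energy) == length(energy_trials),
            length(unique(data$participant_id)) == 1L)
  d <- data
  d$prev_stim <- previous_stimulus(d)
  idx <- match(d$trial, energy_trials)
  use <- d$contrast == 0 & !is.na(d$response) & !is.na(d$prev_stim) &
    !is.na(idx)
  if (any(data$contrast[match(energy_trials, data$trial)] > 0, na.rm = TRUE)) {
    stop("energy rows must correspond to 0%-contrast trials only",
         call. = FALSE)
  }
  d <- d[use, , drop = FALSE]
  E <- energy[idx[use], , drop = FALSE]
  groups <- data.frame(participant = d$participant_id,
                       prev_stim = d$prev_stim,
                       environment = d$environment)
  Z <- zscore_energy(E, groups)
  key <- interaction(groups, drop = TRUE)
  out <- lapply(levels(key), function(g) {
    rows <- which(key == g)
    fb <- fit_bins_batch(Z[rows, , drop = FALSE], d$response[rows] > 0)
    data.frame(participant = groups$participant[rows[1L]],
               environment = groups$environment[rows[1L]],
               prev_stim = groups$prev_stim[rows[1L]],
               orientation_deg = cells$orientation_deg,
               sf_cpd = cells$sf_cpd,
               beta0 = fb$beta0, beta1 = fb$beta1,
               separated = fb$separated)
  })
  do.call(rbind, out)
}

#' Summarize reverse-correlation fits into bias and sensitivity
#'
#' Separation-flagged fits are excluded; then, per (previous stimulus,
#' environment) pool across participants, orientations and spatial
#' frequencies, Tukey-fence outliers are removed from the beta0 and beta1
#' estimates. Bias is the mean beta0 over all cells; sensitivity is the mean
#' beta1 within the clockwise (1 to 89 degrees) and counterclockwise (-89 to
#' -1 degrees) orientation classes (0 and 90 degrees excluded from the
#' classes) and all spatial frequencies. The history effect on sensitivity
#' is, per environment, the sensitivity to clockwise orientation energy
#' after a clockwise previous stimulus minus after a counterclockwise one.
#'
#' @param fits a [fit_revcorr_bins()] data.frame.
#' @param iqr_factor Tukey fence multiplier.
#' @return a `revcorr_summary` list of data.frames: `bias` (participant,
#'   environment, prev_stim, bias), `sensitivity` (ditto plus
#'   `energy_class`), and `history_effect` (participant, environment,
#'   history_sensitivity_effect).
#' @export
summarize_revcorr <- function(fits, iqr_factor = 1.5) {
  f <- fits[!is.na(fits$separated) & !fits$separated, , drop = FALSE]
  pool <- interaction(f$prev_stim, f$environment, drop = TRUE)
  keep0 <- keep1 <- rep(TRUE, nrow(f))
  for (g in levels(pool)) {
    rows <- which(pool == g)
    keep0[rows] <- remove_outliers_iqr(f$beta0[rows], factor = iqr_factor)
    keep1[rows] <- remove_outliers_iqr(f$beta1[rows], factor = iqr_factor)
  }
  mean_by <- function(d, value, extra = NULL) {
    by <- c(list(participant = d$participant, environment = d$environment,
                 prev_stim = d$prev_stim), extra)
    out <- stats::aggregate(d[[value]], by = by, FUN = mean)
    names(out)[names(out) == "x"] <- value
    out
  }
  f0 <- f[keep0, , drop = FALSE]
  f0$bias <- f0$beta0
  bias <- mean_by(f0, "bias")

  f1 <- f[keep1, , drop = FALSE]
  f1$energy_class <- ifelse(f1$orientation_deg >= 1 & f1$orientation_deg <= 89,
                            "cw",
                            ifelse(f1$orientation_deg <= -1 &
                                     f1$orientation_deg >= -89, "ccw", NA))
  f1 <- f1[!is.na(f1$energy_class), , drop = FALSE]
  f1$sensitivity <- f1$beta1
  sens <- mean_by(f1, "sensitivity", extra = list(energy_class = f1$energy_class))

  cw <- sens[sens$energy_class == "cw", , drop = FALSE]
  wide <- merge(cw[cw$prev_stim > 0, c("participant", "environment", "sensitivity")],
                cw[cw$prev_stim < 0, c("participant", "environment", "sensitivity")],
                by = c("participant", "environment"),
                suffixes = c("_prev_cw", "_prev_ccw"))
  wide$history_sensitivity_effect <-
    wide$sensitivity_prev_cw - wide$sensitivity_prev_ccw
  history <- wide[, c("participant", "environment",
                      "history_sensitivity_effect")]
  structure(list(bias = bias, sensitivity = sens, history_effect = history,
                 meta = list(quartiles = "linear interpolation (type 7)",
                             iqr_factor = iqr_factor)),
            class = "revcorr_summary")
}

#' Run the full reverse-correlation pipeline
#'
#' Convenience wrapper: [fit_revcorr_bins()] followed by
#' [summarize_revcorr()].
#'
#' @inheritParams fit_revcorr_bins
#' @inheritParams summarize_revcorr
#' @return a `revcorr_summary` with the bin fits attached as `$bins`.
#' @export
reverse_correlation <- function(data, energy, energy_trials,
                                cells = attr(energy, "cells"),
                                iqr_factor = 1.5) {
  bins <- fit_revcorr_bins(data, energy, energy_trials, cells = cells)
  out <- summarize_revcorr(bins, iqr_factor = iqr_factor)
  out$bins <- bins
  out
}
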