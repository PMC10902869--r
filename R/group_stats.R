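# internal: assemble a one-row contrast result
contrast_row <- function(method, term, statistic, df, df2 = NA_real_,
                         p_value, estimate = NA_real_, n) {
  data.frame(method = method, term = term, statistic = statistic, df = df,
             df2 = df2, p_value = p_value, estimate = estimate, n = n)
}

#' Paired t test
#'
#' @param x,y paired numeric vectors of equal length (>= 3, no missing
#'   pairs).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return a one-row `contrast_result` data.frame: statistic, df, p_value,
#'   estimate (mean difference x - y), n.
#' @export
paired_t <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed", call. = FALSE)
  if (stats::sd(x - y) == 0) {
    stop("zero-variance differences: the paired t statistic is undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = alternative)
  contrast_row("paired t", "x - y", unname(tt$statistic),
               unname(tt$parameter), p_value = tt$p.value,
               estimate = unname(tt$estimate), n = length(x))
}

#' Welch's two-sample t test
#'
#' @param x,y numeric vectors (independent groups).
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return a one-row `contrast_result` data.frame (fractional df).
#' @export
welch_t <- function(x, y, alternative = "two.sided") {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = alternative)
  contrast_row("Welch t", "x - y", unname(tt$statistic), unname(tt$parameter),
               p_value = tt$p.value,
               estimate = unname(diff(rev(tt$estimate))),
               n = length(x) + length(y))
}

#' Repeated-measures ANOVA with two-level within factors
#'
#' Standard within-subject decomposition for 1 to 3 fully crossed two-level
#' factors (each effect tested against its own participant-by-effect error
#' stratum; with two-level factors every F has numerator df 1 and no
#' sphericity correction is needed).
#'
#' @param data data.frame in long format with complete cells: one value per
#'   participant and factor combination.
#' @param dv name of the dependent-variable column.
#' @param id name of the participant column.
#' @param within character vector of 1 to 3 factor column names, each with
#'   exactly two levels.
#' @return a `contrast_result` data.frame with one row per main effect and
#'   interaction: F statistic, df, df2, p_value.
#' @export
rm_anova <- function(data, dv, id, within) {
  stopifnot(length(within) %in% 1:3,
            all(c(dv, id, within) %in% names(data)))
  d <- data
  d[[id]] <- factor(d[[id]])
  for (f in within) {
    d[[f]] <- factor(d[[f]])
    if (nlevels(d[[f]]) != 2L) {
      stop(sprintf("factor '%s' must have exactly two levels", f),
           call. = FALSE)
    }
  }
  counts <- table(d[c(id, within)])
  if (any(counts != 1L)) {
    stop("incomplete within-participant cells: every participant needs ",
         "exactly one value per factor combination", call. = FALSE)
  }
  rhs <- paste(within, collapse = " * ")
  form <- stats::as.formula(sprintf("%s ~ %s + Error(%s/(%s))",
                                    dv, rhs, id, rhs))
  fit <- stats::aov(form, data = d)
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1L]]
    terms_here <- trimws(rownames(tab))
    for (i in seq_along(terms_here)) {
      if (terms_here[i] == "Residuals") next
      rows[[terms_here[i]]] <- contrast_row(
        "rm-ANOVA", terms_here[i], statistic = tab[i, "F value"],
        df = tab[i, "Df"], df2 = tab[nrow(tab), "Df"],
        p_value = tab[i, "Pr(>F)"], n = nlevels(d[[id]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank or product-moment correlation
#'
#' @param x,y numeric vectors (n >= 3).
#' @param method `"spearman"` (rank) or `"pearson"` (product-moment).
#' @return a one-row `contrast_result` data.frame with the coefficient as
#'   `estimate`.
#' @export
correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  contrast_row(method, "cor(x, y)",
               statistic = unname(ct$statistic),
               df = if (!is.null(ct$parameter)) unname(ct$parameter) else NA_real_,
               p_value = ct$p.value, estimate = unname(ct$estimate),
               n = length(x))
}

#' Intercept and slope of a history-weight trajectory
#'
#' Ordinary least-squares line over the series index; the first element of
#' the series (trial or block 1 of the environment) sits at abscissa 0, so
#' the intercept is the starting level and the slope the per-step change.
#'
#' @param weights numeric series of history weights (length >= 2).
#' @param x optional abscissa; defaults to `0, 1, 2, ...`.
#' @return named numeric vector `c(intercept, slope)`.
#' @export
linear_trajectory_fit <- function(weights, x = NULL) {
  if (length(weights) < 2L) {
    stop("trajectory must have at least 2 points", call. = FALSE)
  }
  if (is.null(x)) x <- seq_along(weights) - 1
  stopifnot(length(x) == length(weights))
  co <- stats::coef(stats::lm(weights ~ x))
  c(intercept = unname(co[1L]), slope = unname(co[2L]))
}

#' Block-resolved history-weight trajectory
#'
#' Refits the history model within each block of one environment (lags
#' computed within the environment, rows restricted to the block) and
#' returns the per-block previous-correct lag-1 weight. This block-resolved
#' refit is the package's coarse substitute for trial-resolved weight
#' trajectories and is labeled as such in the output metadata.
#'
#' @param data a single-participant `behavioral_dataset`.
#' @param env environment label.
#' @param lambda lasso penalty.
#' @param n_lags history lags.
#' @param lapse_grid lapse search passed to [fit_history_model()]; default
#'   fixes lapses at 0 for stability on 100-trial blocks.
#' @return a data.frame (block, prev_correct1) with attribute `"source"`.
#' @export
block_history_trajectory <- function(data, env, lambda = 0.001, n_lags = 7L,
                                     lapse_grid = 0) {
  d <- data[data$environment == env, , drop = FALSE]
  d <- d[order(d$trial), , drop = FALSE]
  dm_all <- build_design_matrix(d, env = env, n_lags = n_lags)
  blocks <- d$block[seq.int(n_lags + 1L, nrow(d))]
  blocks <- blocks[!is.na(d$response[seq.int(n_lags + 1L, nrow(d))])]
  out <- lapply(unique(blocks), function(b) {
    rows <- blocks == b
    dm <- dm_all
    dm$X <- dm_all$X[rows, , drop = FALSE]
    dm$y <- dm_all$y[rows]
    fit <- suppressWarnings(fit_history_model(dm, lambda = lambda,
                                              lapse_grid = lapse_grid))
    data.frame(block = b,
               prev_correct1 = unname(fit$weights["s1"] + fit$weights["r1"]),
               converged = fit$converged)
  })
  out <- do.call(rbind, out)
  attr(out, "source") <- "block-resolved refit (not trial-resolved)"
  out
}
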