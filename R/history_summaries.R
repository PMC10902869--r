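# helper: previous-trial stimulus orientation within environment (NA at the
# first trial of each environment); used by the conditioned summaries and the
# reverse-correlation pipeline
previous_stimulus <- function(data) {
  ord <- order(data$trial)
  prev <- rep(NA_real_, nrow(data))
  o <- data$orientation[ord]
  e <- data$environment[ord]
  prev[ord[-1]] <- ifelse(e[-1] == e[-length(e)], o[-length(o)], NA)
  prev
}

#' Accuracy summaries of a behavioral dataset
#'
#' @param data a `behavioral_dataset` (one or many participants). Missed
#'   responses (`NA`) are dropped; cells without trials are absent from the
#'   tables rather than reported as zero.
#' @param low_contrast_max low-contrast trials are those with
#'   `contrast < low_contrast_max` (default 0.06, i.e. contrasts 0, 0.02
#'   and 0.04).
#' @return a list of data.frames: `by_block` (participant, block, n,
#'   accuracy), `by_contrast_env`, and `low_contrast` (per participant and
#'   environment).
#' @export
accuracy_summaries <- function(data, low_contrast_max = 0.06) {
  stopifnot(all(c("participant_id", "block", "contrast", "environment",
                  "is_correct") %in% names(data)))
  d <- data[!is.na(data$response), , drop = FALSE]
  agg <- function(values, f) {
    out <- stats::aggregate(values, by = f, FUN = function(z)
      c(n = length(z), accuracy = mean(z)))
    cbind(out[setdiff(names(out), "x")],
          n = out$x[, "n"], accuracy = out$x[, "accuracy"])
  }
  by_block <- agg(d$is_correct,
                  list(participant_id = d$participant_id, block = d$block))
  by_contrast_env <- agg(d$is_correct,
                         list(participant_id = d$participant_id,
                              environment = d$environment,
                              contrast = d$contrast))
  low <- d[d$contrast < low_contrast_max, , drop = FALSE]
  low_contrast <- agg(low$is_correct,
                      list(participant_id = low$participant_id,
                           environment = low$environment))
  list(by_block = by_block[order(by_block$participant_id, by_block$block), ],
       by_contrast_env = by_contrast_env,
       low_contrast = low_contrast)
}

#' Psychometric curves conditioned on the previous stimulus
#'
#' Empirical probability of a clockwise response as a function of signed
#' contrast, split by environment and by the orientation of the previous
#' stimulus (within environment; the first trial of each environment is
#' dropped). If history fits are supplied, each trial's model-predicted
#' clockwise probability is averaged within the same bins.
#'
#' @param data a single-participant `behavioral_dataset`.
#' @param fits optional named list `list(neutral = , repeating = )` of
#'   [fit_history_model()] results.
#' @return a data.frame: `environment`, `prev_stim`, `signed_contrast`, `n`,
#'   `p_cw` and (with fits) `p_cw_model`.
#' @export
conditioned_psychometric <- function(data, fits = NULL) {
  d <- data
  d$prev_stim <- previous_stimulus(d)
  d <- d[!is.na(d$prev_stim) & !is.na(d$response), , drop = FALSE]
  d$cw <- as.numeric(d$response == 1)
  if (!is.null(fits)) {
    d$p_model <- NA_real_
    for (e in names(fits)) {
      fit <- fits[[e]]
      dm <- build_design_matrix(data, env = e, n_lags = fit$n_lags)
      eta <- cbind(1, dm$X) %*% fit$weights
      p <- fit$lapse_cw + (1 - fit$lapse_cw - fit$lapse_ccw) * stats::plogis(eta)
      # rows of dm correspond to analyzable trials; align through trial ids
      de <- data[data$environment == e, , drop = FALSE]
      de <- de[order(de$trial), , drop = FALSE]
      keep <- seq.int(fit$n_lags + 1L, nrow(de))
      keep <- keep[!is.na(de$response[keep])]
      d$p_model[match(de$trial[keep], d$trial)] <- p
    }
  }
  groups <- list(environment = d$environment, prev_stim = d$prev_stim,
                 signed_contrast = d$signed_contrast)
  out <- stats::aggregate(d$cw, by = groups, FUN = function(z)
    c(n = length(z), p = mean(z)))
  res <- cbind(out[1:3], n = out$x[, "n"], p_cw = out$x[, "p"])
  if (!is.null(fits)) {
    pm <- stats::aggregate(d$p_model, by = groups,
                           FUN = function(z) mean(z, na.rm = TRUE))
    res$p_cw_model <- pm$x[match(interaction(res$environment, res$prev_stim,
                                             res$signed_contrast),
                                 interaction(pm$environment, pm$prev_stim,
                                             pm$signed_contrast))]
  }
  res[order(res$environment, res$prev_stim, res$signed_contrast), ]
}

#' Apply the session exclusion criteria
#'
#' Rule 1: minimum overall accuracy of 65% (responded trials). Rule 2: at
#' most 5% of the session's trials missed (60 of 1200 at the default design).
#' Rule 3: minimum accuracy of 65% in each environment separately.
#'
#' @param data a `behavioral_dataset` with one or many participants.
#' @param min_accuracy minimum proportion correct.
#' @param max_missed_frac maximum fraction of missed responses.
#' @return a list: `data` (retained participants' trials) and `report` (one
#'   row per participant: accuracies, missed count, `excluded`,
#'   `rules_fired`).
#' @export
apply_exclusion_criteria <- function(data, min_accuracy = 0.65,
                                     max_missed_frac = 0.05) {
  ids <- unique(data$participant_id)
  rows <- lapply(ids, function(id) {
    d <- data[data$participant_id == id, , drop = FALSE]
    n_missed <- sum(is.na(d$response))
    resp <- d[!is.na(d$response), , drop = FALSE]
    acc <- mean(resp$is_correct)
    acc_env <- vapply(split(resp$is_correct, resp$environment), mean,
                      numeric(1))
    fired <- c(
      if (acc < min_accuracy) 1L,
      if (n_missed > max_missed_frac * nrow(d)) 2L,
      if (any(acc_env < min_accuracy)) 3L
    )
    data.frame(participant_id = id, accuracy = acc, n_missed = n_missed,
               accuracy_neutral = acc_env[["neutral"]],
               accuracy_repeating = acc_env[["repeating"]],
               excluded = length(fired) > 0L,
               rules_fired = paste(fired, collapse = ","))
  })
  report <- do.call(rbind, rows)
  keep_ids <- report$participant_id[!report$excluded]
  list(data = data[data$participant_id %in% keep_ids, , drop = FALSE],
       report = report)
}
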