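#' Full analysis-pipeline configuration
#'
#' Defaults mirror the full session design: 6 blocks x 100 trials per environment,
#' repetition probability 0.8 +/- 0.02 in the repeating environment, six
#' contrast levels, 7 history lags, lasso penalty 0.001, 1.5 x IQR outlier
#' fences. The energy raster defaults to a reduced 64 x 64 grid (the full
#' 180 x 9 filter bank is kept) for desk-scale batch processing. Observer
#' parameters are drawn per participant from the stated population ranges.
#'
#' @param n_participants number of synthetic participants.
#' @param design a [session_config()] list.
#' @param raster_px side length of the analysis raster.
#' @param n_lags,lambda history-model settings.
#' @param iqr_factor Tukey fence multiplier.
#' @param observer_population list of population means/sds used to draw each
#'   participant's generative parameters.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_participants = 20L,
                            design = session_config(),
                            raster_px = 64L,
                            n_lags = 7L, lambda = 0.001,
                            iqr_factor = 1.5,
                            observer_population = list(
                              intercept_sd = 0.1,
                              slope_mean = 15, slope_sd = 2,
                              lapse_max = 0.05,
                              w_stim1_mean = 0.25, w_stim1_sd = 0.1,
                              w_choice1_mean = 0.15, w_choice1_sd = 0.1,
                              kernel_decay = 0.5,
                              energy_beta = 1,
                              gain_consistent = 1.5,
                              gain_inconsistent = 0.5)) {
  check_scalar(n_participants, "n_participants", lo = 1)
  cfg <- list(n_participants = as.integer(n_participants), design = design,
              raster_px = as.integer(raster_px), n_lags = n_lags,
              lambda = lambda, iqr_factor = iqr_factor,
              observer_population = observer_population)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through JSON.
#'
#' @param config a [pipeline_config()] list.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$design <- do.call(session_config, raw$design)
  do.call(pipeline_config, raw)
}

# internal: draw one participant's generative observer parameters
draw_observer <- function(pop, seed) {
  set.seed(seed)
  observer_params(
    intercept = stats::rnorm(1, 0, pop$intercept_sd),
    slope = max(1, stats::rnorm(1, pop$slope_mean, pop$slope_sd)),
    lapse_cw = stats::runif(1, 0, pop$lapse_max),
    lapse_ccw = stats::runif(1, 0, pop$lapse_max),
    w_stim = history_kernel(stats::rnorm(1, pop$w_stim1_mean, pop$w_stim1_sd),
                            pop$kernel_decay),
    w_choice = history_kernel(stats::rnorm(1, pop$w_choice1_mean,
                                           pop$w_choice1_sd),
                              pop$kernel_decay),
    energy_beta = pop$energy_beta,
    gain_consistent = pop$gain_consistent,
    gain_inconsistent = pop$gain_inconsistent)
}

#' Run the end-to-end synthetic pipeline
#'
#' Stages: session designs -> stimulus rendering and orientation energies
#' (0%-contrast trials) -> simulated behavior -> exclusion filters ->
#' history-model fits and summaries -> reverse correlation -> group
#' statistics. When `out_dir` is given, tidy CSV summaries and a JSON
#' manifest (stage seeds and file hashes) are written; rerunning with the
#' same config and seed reproduces the files byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return a `pipeline_result` list: `designs`, `behavior`, `exclusions`,
#'   `history` (per-participant fits and summaries), `revcorr`,
#'   `group_stats`, `manifest`.
#' @export
run_end_to_end <- function(config = pipeline_config(), seed = 1L,
                           out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  ids <- sprintf("sim%02d", seq_len(config$n_participants))

  designs <- stage("design", lapply(seq_along(ids), function(i) {
    build_session(config$design, seed = derive_seed(seed, paste0("design:", i)))
  }))

  sp <- reduced_stimulus_params(config$raster_px)
  bank <- stage("filter-bank", build_filter_bank(sp))

  energies <- stage("energy", lapply(seq_along(ids), function(i) {
    des <- designs[[i]]
    zt <- des$trial[des$contrast == 0]
    imgs <- lapply(zt, function(t) {
      render_stimulus(des$orientation[des$trial == t], 0, sp,
                      seed = derive_seed(seed, sprintf("stim:%d:%d", i, t)))
    })
    E <- compute_energy_profiles(imgs, bank)
    list(trials = zt, energy = E,
         net = cbind(trial = zt, class_net_energies(E)))
  }))

  behavior <- stage("simulate", {
    dat <- lapply(seq_along(ids), function(i) {
      obs <- draw_observer(config$observer_population,
                           derive_seed(seed, paste0("observer-params:", i)))
      simulate_session(obs, designs[[i]], energies = energies[[i]]$net,
                       seed = derive_seed(seed, paste0("observer:", i)),
                       participant_id = ids[i])
    })
    do.call(rbind, dat)
  })

  exclusions <- stage("exclusions", apply_exclusion_criteria(behavior))
  kept <- unique(exclusions$data$participant_id)

  history <- stage("history-fit", lapply(kept, function(id) {
    d <- exclusions$data[exclusions$data$participant_id == id, , drop = FALSE]
    fn <- fit_history_model(build_design_matrix(d, "neutral", config$n_lags),
                            lambda = config$lambda)
    fr <- fit_history_model(build_design_matrix(d, "repeating", config$n_lags),
                            lambda = config$lambda)
    list(participant = id, neutral = fn, repeating = fr,
         summary = derive_history_summaries(fn, fr),
         accuracy = accuracy_summaries(d))
  }))
  names(history) <- kept

  revcorr <- stage("revcorr", {
    bins <- do.call(rbind, lapply(kept, function(id) {
      i <- match(id, ids)
      d <- exclusions$data[exclusions$data$participant_id == id, , drop = FALSE]
      fit_revcorr_bins(d, energies[[i]]$energy, energies[[i]]$trials,
                       cells = bank$cells)
    }))
    s <- summarize_revcorr(bins, iqr_factor = config$iqr_factor)
    s$bins <- bins
    s
  })

  group <- stage("group-stats", pipeline_group_stats(history, revcorr))

  result <- list(designs = designs, behavior = behavior,
                 exclusions = exclusions, history = history,
                 revcorr = revcorr, group_stats = group)
  result$manifest <- list(
    package = "histbias", seed = seed,
    n_participants = config$n_participants,
    stages = c("design", "filter-bank", "energy", "simulate", "exclusions",
               "history-fit", "revcorr", "group-stats"),
    retained_participants = kept)
  class(result) <- "pipeline_result"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      behavior = write_trial_table(behavior, file.path(out_dir, "behavior.csv")),
      exclusions = write_plain_csv(exclusions$report,
                                   file.path(out_dir, "exclusions.csv")),
      history = write_plain_csv(
        do.call(rbind, lapply(names(history), function(id)
          cbind(participant = id, history[[id]]$summary))),
        file.path(out_dir, "history_summaries.csv")),
      revcorr_bias = write_plain_csv(revcorr$bias,
                                     file.path(out_dir, "revcorr_bias.csv")),
      revcorr_sensitivity = write_plain_csv(
        revcorr$sensitivity, file.path(out_dir, "revcorr_sensitivity.csv")),
      revcorr_history_effect = write_plain_csv(
        revcorr$history_effect,
        file.path(out_dir, "revcorr_history_effect.csv")),
      group_stats = write_plain_csv(group,
                                    file.path(out_dir, "group_stats.csv")))
    result$manifest$files <-
      lapply(stats::setNames(as.list(files), names(files)), function(f)
        list(path = basename(f), md5 = unname(tools::md5sum(f))))
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}

# internal: the group-level contrasts reported by the pipeline
pipeline_group_stats <- function(history, revcorr) {
  out <- list()
  if (length(history) >= 3L) {
    pc1_n <- vapply(history, function(h) h$summary$prev_correct_neutral[1L],
                    numeric(1))
    pc1_r <- vapply(history, function(h) h$summary$prev_correct_repeating[1L],
                    numeric(1))
    out$adaptation <- cbind(contrast = "prev-correct lag-1: repeating vs neutral",
                            paired_t(pc1_r, pc1_n))
    # adaptation vs low-contrast accuracy in the repeating environment
    acc_low <- vapply(history, function(h) {
      lc <- h$accuracy$low_contrast
      lc$accuracy[lc$environment == "repeating"][1L]
    }, numeric(1))
    out$adaptation_accuracy <- cbind(
      contrast = "adaptation vs low-contrast accuracy (repeating)",
      correlation(pc1_r - pc1_n, acc_low, method = "spearman"))
  }
  b <- revcorr$bias
  if (length(unique(b$participant)) >= 3L && nrow(b) > 0L) {
    complete <- stats::aggregate(list(n = b$bias),
                                 by = list(participant = b$participant),
                                 FUN = length)
    full <- complete$participant[complete$n == 4L]
    bb <- b[b$participant %in% full, , drop = FALSE]
    if (length(full) >= 3L) {
      out$bias_anova <- cbind(contrast = "bias: prev_stim x environment",
                              rm_anova(bb, dv = "bias", id = "participant",
                                       within = c("prev_stim", "environment")))
    }
  }
  s <- revcorr$sensitivity
  if (nrow(s) > 0L) {
    complete <- stats::aggregate(list(n = s$sensitivity),
                                 by = list(participant = s$participant),
                                 FUN = length)
    full <- complete$participant[complete$n == 8L]
    ss <- s[s$participant %in% full, , drop = FALSE]
    if (length(full) >= 3L) {
      out$sensitivity_anova <- cbind(
        contrast = "sensitivity: class x prev_stim x environment",
        rm_anova(ss, dv = "sensitivity", id = "participant",
                 within = c("energy_class", "prev_stim", "environment")))
    }
  }
  do.call(rbind, out)
}

#' Write / read the per-trial CSV dialect
#'
#' One row per trial: `participant_id`, `environment`, `block`, `trial`,
#' `orientation`, `contrast`, `correct_label` and, when present, `response`
#' and `is_correct`. UTF-8, header required, `.` decimal separator.
#'
#' @param data a design or behavioral data.frame.
#' @param path file path.
#' @return `read_trial_table` returns a data.frame.
#' @export
write_trial_table <- function(data, path) {
  cols <- intersect(c("participant_id", "environment", "block", "trial",
                      "orientation", "contrast", "correct_label", "response",
                      "is_correct"), names(data))
  utils::write.csv(as.data.frame(data)[cols], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  required <- c("environment", "block", "trial", "orientation", "contrast",
                "correct_label")
  missing_f <- setdiff(required, names(d))
  if (length(missing_f)) {
    stop("trial table is missing column(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  d
}

# internal
write_plain_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an orientation-energy table in long format
#'
#' @param energy trials x cells matrix (see [compute_energy_profiles()]).
#' @param trials trial ids for the rows.
#' @param path file path.
#' @param cells cell grid; defaults to the `"cells"` attribute.
#' @return the path, invisibly.
#' @export
write_energy_table <- function(energy, trials, path,
                               cells = attr(energy, "cells")) {
  stopifnot(!is.null(cells), nrow(energy) == length(trials))
  long <- data.frame(trial = rep(trials, each = nrow(cells)),
                     orientation_deg = rep(cells$orientation_deg,
                                           length(trials)),
                     sf_cpd = rep(cells$sf_cpd, length(trials)),
                     energy = as.vector(t(energy)))
  utils::write.csv(long, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Generate deterministic synthetic fixtures
#'
#' `tiny`: 2 participants, 2 blocks per environment, 64 x 64 raster --
#' suitable for fast checks. `standard`: 20 participants at the full
#' 12-block session scale.
#'
#' @param size `"tiny"` or `"standard"`.
#' @param seed integer seed.
#' @param out_dir directory to write `design_*.csv` and `behavior_*.csv`.
#' @return the configuration used, invisibly.
#' @export
generate_fixtures <- function(size = c("tiny", "standard"), seed = 1L,
                              out_dir) {
  size <- match.arg(size)
  cfg <- if (size == "tiny") {
    pipeline_config(n_participants = 2L,
                    design = session_config(n_blocks_per_env = 2L),
                    raster_px = 64L)
  } else {
    pipeline_config(n_participants = 20L)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("sim%02d", seq_len(cfg$n_participants))
  for (i in seq_along(ids)) {
    des <- build_session(cfg$design, seed = derive_seed(seed, paste0("design:", i)))
    obs <- draw_observer(cfg$observer_population,
                         derive_seed(seed, paste0("observer-params:", i)))
    # fixtures carry the history-only observer (no rendering dependency)
    obs$energy_beta <- 0
    obs$gain_consistent <- 1
    obs$gain_inconsistent <- 1
    beh <- simulate_session(obs, des,
                            seed = derive_seed(seed, paste0("observer:", i)),
                            participant_id = ids[i])
    write_trial_table(cbind(participant_id = ids[i], as.data.frame(des)),
                      file.path(out_dir, sprintf("design_%s.csv", ids[i])))
    write_trial_table(beh, file.path(out_dir, sprintf("behavior_%s.csv", ids[i])))
  }
  invisible(cfg)
}
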