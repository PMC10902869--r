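#' The 2 x 6 condition grid of a session
#'
#' Conditions are the crossing of grating orientation (sign: `+1` = clockwise
#' +45 degrees, `-1` = counterclockwise -45 degrees) with the six Michelson
#' contrast levels of the target grating.
#'
#' @param contrasts numeric vector of admissible Michelson contrasts.
#' @return a data.frame with columns `orientation` and `contrast`, one row per
#'   condition (12 rows with the default contrasts).
#' @export
condition_grid <- function(contrasts = c(0, 0.02, 0.04, 0.06, 0.12, 0.18)) {
  stopifnot(length(contrasts) >= 1L, !anyDuplicated(contrasts),
            all(contrasts >= 0), all(contrasts <= 1))
  out <- expand.grid(orientation = c(-1, 1), contrast = contrasts,
                     KEEP.OUT.ATTRS = FALSE)
  out[order(out$contrast, out$orientation), , drop = FALSE]
}

new_trial_sequence <- function(orientation, contrast, environment, generator,
                               seed, correct_label = NA_real_) {
  n <- length(orientation)
  out <- data.frame(
    trial = seq_len(n),
    environment = rep(environment, n),
    orientation = orientation,
    contrast = contrast,
    correct_label = rep_len(correct_label, n)
  )
  attr(out, "generator") <- generator
  attr(out, "seed") <- seed
  class(out) <- c("trial_sequence", "data.frame")
  out
}

#' Generate a serially counterbalanced condition sequence
#'
#' Constructs a sequence in which every condition is preceded (to within one
#' count) equally often by every other condition, including itself. The
#' sequence is an Eulerian path on the complete directed multigraph over the
#' conditions: each ordered condition pair is used either `m` or `m + 1`
#' times, with the extra transitions allocated so that condition counts are
#' as equal as possible. Candidate sequences are resampled (seed incremented)
#' until the empirical orientation repetition frequency is within
#' `rep_tolerance` of 0.5.
#'
#' @param n_trials number of trials; must exceed `nrow(conditions)^2` so that
#'   every ordered transition can occur at least once.
#' @param conditions data.frame of conditions, as [condition_grid()].
#' @param seed integer seed.
#' @param rep_tolerance admissible deviation of the orientation repetition
#'   frequency from 0.5.
#' @param max_iter maximum number of resampling attempts.
#' @return a `trial_sequence` data.frame (columns `trial`, `environment`,
#'   `orientation`, `contrast`, `correct_label`); the realized transition
#'   count table is attached as attribute `"transition_counts"`.
#' @export
generate_counterbalanced_sequence <- function(n_trials,
                                              conditions = condition_grid(),
                                              seed = 1L,
                                              rep_tolerance = 0.02,
                                              max_iter = 100L) {
  k <- nrow(conditions)
  check_scalar(n_trials, "n_trials", lo = 2)
  if (k > 1L && (n_trials - 1) < k * k) {
    stop(sprintf(paste0("n_trials = %d is too small to visit every ordered ",
                        "transition among %d conditions at least once ",
                        "(need n_trials > %d)"), n_trials, k, k * k),
         call. = FALSE)
  }
  for (it in seq_len(max_iter)) {
    seed_it <- seed + it - 1L
    set.seed(seed_it)
    idx <- eulerian_condition_path(n_trials, k)
    ori <- conditions$orientation[idx]
    if (k == 1L) break
    rep_freq <- mean(ori[-1] == ori[-n_trials])
    if (abs(rep_freq - 0.5) <= rep_tolerance) break
    if (it == max_iter) {
      stop(sprintf(paste0("counterbalanced sequence: repetition frequency ",
                          "%.4f not within %.3f of 0.5 after %d attempts"),
                   rep_freq, rep_tolerance, max_iter), call. = FALSE)
    }
  }
  out <- new_trial_sequence(conditions$orientation[idx],
                            conditions$contrast[idx],
                            environment = "neutral",
                            generator = "counterbalanced", seed = seed_it)
  attr(out, "transition_counts") <-
    table(factor(idx[-n_trials], levels = seq_len(k)),
          factor(idx[-1], levels = seq_len(k)))
  out
}

# internal: Eulerian path over k conditions with transition counts m or m + 1.
# The n_trials - 1 transitions decompose as m complete ordered-pair sets plus
# r extra edges laid out as a 0/1 matrix with (near-)equal row and column
# sums; equal row/column extras per node make the walk an Eulerian circuit,
# and starting at a minimum-extra node keeps condition counts maximally even.
eulerian_condition_path <- function(n_trials, k) {
  if (k == 1L) return(rep(1L, n_trials))
  t_edges <- n_trials - 1L
  m <- t_edges %/% (k * k)
  r <- t_edges %% (k * k)
  extra <- rep(r %/% k, k)
  hot <- sample_int(seq_len(k), r %% k)
  extra[hot] <- extra[hot] + 1L
  cnt <- matrix(m, k, k)
  if (r > 0) cnt <- cnt + binary_matrix_with_margins(extra, extra)
  start <- sample_int(which(extra == min(extra)), 1L)

  # Hierholzer's algorithm with randomized successor order
  succ <- vector("list", k)
  for (i in seq_len(k)) {
    s <- rep.int(seq_len(k), cnt[i, ])
    succ[[i]] <- if (length(s) > 1L) sample(s) else s
  }
  ptr <- rep(1L, k)
  stack <- integer(t_edges + 1L); stack[1L] <- start; sp <- 1L
  path <- integer(t_edges + 1L); pp <- 0L
  while (sp > 0L) {
    v <- stack[sp]
    if (ptr[v] <= length(succ[[v]])) {
      u <- succ[[v]][ptr[v]]
      ptr[v] <- ptr[v] + 1L
      sp <- sp + 1L
      stack[sp] <- u
    } else {
      pp <- pp + 1L
      path[pp] <- v
      sp <- sp - 1L
    }
  }
  if (pp != t_edges + 1L) stop("internal error: Eulerian circuit incomplete")
  rev(path)
}

# internal: random 0/1 matrix with prescribed row and column sums
# (Gale-Ryser greedy: rows in random order, ones to the columns with the
# largest remaining demand, random tie-break).
binary_matrix_with_margins <- function(rows, cols) {
  k <- length(rows)
  x <- matrix(0L, k, k)
  demand <- cols
  for (i in sample(seq_len(k))) {
    if (rows[i] == 0L) next
    ord <- order(demand + stats::runif(k), decreasing = TRUE)
    take <- ord[seq_len(rows[i])]
    if (any(demand[take] <= 0L)) stop("internal error: margin allocation infeasible")
    x[i, take] <- 1L
    demand[take] <- demand[take] - 1L
  }
  x
}

#' Generate a Markov orientation sequence with a target repetition probability
#'
#' Orientations are drawn sequentially: the first uniformly, each subsequent
#' one repeating the previous with probability `p_rep`. Whole sequences are
#' resampled (seed incremented) until the empirical repetition frequency is
#' within `tolerance` of `p_rep`.
#'
#' @param n_trials number of trials (>= 1).
#' @param p_rep target repetition probability in `[0, 1]`.
#' @param tolerance admissible deviation of the empirical repetition
#'   frequency from `p_rep` (> 0).
#' @param seed integer seed.
#' @param max_iter maximum number of resampling attempts.
#' @return a `trial_sequence` with orientations only (`contrast` is `NA`);
#'   the accepted empirical repetition frequency is attached as attribute
#'   `"rep_freq"`.
#' @export
generate_markov_sequence <- function(n_trials, p_rep = 0.8, tolerance = 0.02,
                                     seed = 1L, max_iter = 10000L) {
  check_scalar(n_trials, "n_trials", lo = 1)
  check_scalar(p_rep, "p_rep", lo = 0, hi = 1)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("invalid value for 'tolerance': must be > 0", call. = FALSE)
  }
  freq <- NA_real_
  for (it in seq_len(max_iter)) {
    seed_it <- seed + it - 1L
    set.seed(seed_it)
    first <- sample(c(-1, 1), 1L)
    if (n_trials == 1L) {
      ori <- first
      freq <- NA_real_
      break
    }
    flips <- ifelse(stats::runif(n_trials - 1L) < p_rep, 1, -1)
    ori <- first * cumprod(c(1, flips))
    freq <- mean(ori[-1] == ori[-n_trials])
    if (abs(freq - p_rep) <= tolerance) break
    if (it == max_iter) {
      stop(sprintf(paste0("Markov sequence: achieved repetition frequency ",
                          "%.4f outside %.3f +/- %.3f after %d attempts"),
                   freq, p_rep, tolerance, max_iter), call. = FALSE)
    }
  }
  out <- new_trial_sequence(ori, NA_real_, environment = "repeating",
                            generator = "markov", seed = seed_it)
  attr(out, "rep_freq") <- freq
  attr(out, "p_rep") <- p_rep
  out
}

#' Assign correct (rewarded) response labels to a trial sequence
#'
#' Trials with a visible grating (`contrast > 0`) are rewarded for reporting
#' the grating orientation. On 0%-contrast trials the rewarded response is
#' drawn uniformly in the neutral environment, whereas in the repeating
#' environment it is the trial's latent orientation, i.e. the state of the
#' same Markov chain that generated the sequence, so that the sequential
#' regularity extends to trials without a target.
#'
#' @param seq a `trial_sequence` with `orientation`, `contrast` and
#'   `environment` columns assigned.
#' @param seed integer seed (used for the neutral uniform draws).
#' @return the sequence with `correct_label` filled in.
#' @export
assign_correct_labels <- function(seq, seed = 1L) {
  stopifnot(is.data.frame(seq),
            all(c("orientation", "contrast", "environment") %in% names(seq)))
  if (anyNA(seq$orientation) || anyNA(seq$contrast)) {
    stop("sequence must have orientations and contrasts assigned", call. = FALSE)
  }
  set.seed(seed)
  lab <- seq$orientation
  zero_neutral <- seq$contrast == 0 & seq$environment == "neutral"
  lab[zero_neutral] <- sample(c(-1, 1), sum(zero_neutral), replace = TRUE)
  seq$correct_label <- lab
  seq
}

#' Default session design parameters
#'
#' @param n_blocks_per_env blocks per environment (default 6).
#' @param trials_per_block trials per block (default 100).
#' @param contrasts admissible Michelson contrast levels.
#' @param p_rep stimulus repetition probability of the repeating environment.
#' @param tolerance admissible deviation of the empirical repetition
#'   frequency from `p_rep`.
#' @return a named list of design parameters.
#' @export
session_config <- function(n_blocks_per_env = 6L, trials_per_block = 100L,
                           contrasts = c(0, 0.02, 0.04, 0.06, 0.12, 0.18),
                           p_rep = 0.8, tolerance = 0.02) {
  check_scalar(n_blocks_per_env, "n_blocks_per_env", lo = 1)
  check_scalar(trials_per_block, "trials_per_block", lo = 1)
  check_scalar(p_rep, "p_rep", lo = 0, hi = 1)
  if (!is.numeric(tolerance) || tolerance <= 0) {
    stop("invalid value for 'tolerance': must be > 0", call. = FALSE)
  }
  if (!is.numeric(contrasts) || anyDuplicated(contrasts) ||
      any(contrasts < 0 | contrasts > 1)) {
    stop("invalid value for 'contrasts': distinct values in [0, 1]",
         call. = FALSE)
  }
  list(n_blocks_per_env = as.integer(n_blocks_per_env),
       trials_per_block = as.integer(trials_per_block),
       contrasts = contrasts, p_rep = p_rep, tolerance = tolerance)
}

#' Build a full two-environment session design
#'
#' A session consists of `n_blocks_per_env` blocks in the neutral environment
#' (counterbalanced conditions, repetition probability 0.5) followed --
#' always in this order -- by the same number of blocks in the repeating
#' environment (Markov orientation sequence with repetition probability
#' `p_rep`; contrasts drawn as a balanced permutation independent of the
#' orientation chain). Correct labels are assigned per
#' [assign_correct_labels()]. Blocks are numbered 1-based across the session.
#'
#' @param config a list from [session_config()].
#' @param seed integer master seed for the session.
#' @return a `session_design` data.frame with columns `environment`, `block`,
#'   `trial`, `orientation`, `contrast`, `correct_label`.
#' @export
build_session <- function(config = session_config(), seed = 1L) {
  required <- c("n_blocks_per_env", "trials_per_block", "contrasts",
                "p_rep", "tolerance")
  missing_f <- setdiff(required, names(config))
  if (length(missing_f)) {
    stop("config is missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  cfg <- do.call(session_config, config[required])
  n_env <- cfg$n_blocks_per_env * cfg$trials_per_block
  cond <- condition_grid(cfg$contrasts)

  neutral <- neutral_environment(n_env, cond, derive_seed(seed, "neutral"))
  neutral <- assign_correct_labels(neutral, derive_seed(seed, "neutral-labels"))

  rep_seq <- generate_markov_sequence(n_env, cfg$p_rep, cfg$tolerance,
                                      seed = derive_seed(seed, "repeating"))
  set.seed(derive_seed(seed, "repeating-contrasts"))
  pool <- rep_len(rep(cfg$contrasts,
                      each = ceiling(n_env / length(cfg$contrasts))), n_env)
  rep_seq$contrast <- pool[sample.int(n_env)]
  rep_seq <- assign_correct_labels(rep_seq, derive_seed(seed, "repeating-labels"))

  out <- rbind(as.data.frame(neutral), as.data.frame(rep_seq))
  out$trial <- seq_len(nrow(out))
  out$block <- rep(seq_len(2L * cfg$n_blocks_per_env),
                   each = cfg$trials_per_block)
  out <- out[, c("environment", "block", "trial", "orientation", "contrast",
                 "correct_label")]
  attr(out, "config") <- cfg
  attr(out, "seed") <- seed
  attr(out, "p_rep_target") <- cfg$p_rep
  attr(out, "p_rep_tolerance") <- cfg$tolerance
  class(out) <- c("session_design", "data.frame")
  out
}

# internal: neutral environment; counterbalanced when the trial count allows
# every ordered transition, otherwise a balanced random permutation of the
# condition grid (tiny designs).
neutral_environment <- function(n_env, cond, seed) {
  k <- nrow(cond)
  if (n_env - 1 >= k * k) {
    generate_counterbalanced_sequence(n_env, cond, seed = seed)
  } else {
    set.seed(seed)
    pool <- rep_len(sample(seq_len(k)), n_env)
    idx <- pool[sample.int(n_env)]
    new_trial_sequence(cond$orientation[idx], cond$contrast[idx],
                       environment = "neutral",
                       generator = "balanced-permutation", seed = seed)
  }
}

#' @export
print.session_design <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("session design: %d trials, %d blocks (%d per environment)\n",
              nrow(x), 2L * cfg$n_blocks_per_env, cfg$n_blocks_per_env))
  cat(sprintf("  contrasts: %s\n", paste(cfg$contrasts, collapse = ", ")))
  cat(sprintf("  repeating p_rep target %.2f +/- %.2f\n",
              cfg$p_rep, cfg$tolerance))
  invisible(x)
}
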