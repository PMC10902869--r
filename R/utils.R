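#' Derive a stage seed from a master seed and a tag
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the master seed and a short stage tag, so that a single integer
#' reproduces an entire analysis while stages remain independently
#' re-runnable.
#'
#' @param master integer master seed.
#' @param tag character stage tag (e.g. `"design"`, `"observer:3"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  m <- 2147483629 # largest prime below 2^31; keeps products < 2^53
  h <- abs(as.numeric(master)) %% m
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# internal: consistent error for bad scalar arguments, naming the field
check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("invalid value for '%s': must be a single number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

# internal: sample() without its n == 1 surprise
sample_int <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
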