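#' Stimulus rendering parameters
#'
#' The stimulus is a sinusoidal grating (spatial frequency `grating_sf`,
#' orientation +/-45 degrees from vertical, random phase) embedded in
#' Gaussian white noise that is smoothed with a Gaussian kernel and scaled so
#' that the standard deviation of the smoothed noise luminance equals
#' `noise_contrast` relative to the mean-gray background. The composite is
#' windowed by a raised-cosine circular aperture and clipped to `[0, 1]`.
#'
#' @param grating_sf grating spatial frequency, cycles/degree.
#' @param noise_contrast RMS contrast of the smoothed noise (relative to the
#'   0.5 background luminance).
#' @param noise_smooth_sd standard deviation of the Gaussian smoothing
#'   kernel, degrees.
#' @param aperture_radius radius of the circular aperture, degrees.
#' @param pixels_per_degree raster resolution; must be at least
#'   `4 * grating_sf` (Nyquist for the target frequency with margin).
#' @param aperture_edge width of the raised-cosine aperture edge, as a
#'   fraction of the radius.
#' @return a `stimulus_params` list.
#' @export
stimulus_params <- function(grating_sf = 1, noise_contrast = 0.3,
                            noise_smooth_sd = 0.08, aperture_radius = 5,
                            pixels_per_degree = 24, aperture_edge = 0.1) {
  check_scalar(grating_sf, "grating_sf", lo = 1e-6)
  check_scalar(noise_contrast, "noise_contrast", lo = 0)
  check_scalar(noise_smooth_sd, "noise_smooth_sd", lo = 0)
  check_scalar(aperture_radius, "aperture_radius", lo = 1e-6)
  check_scalar(aperture_edge, "aperture_edge", lo = 0, hi = 1)
  if (pixels_per_degree < 4 * grating_sf) {
    stop("pixels_per_degree must be >= 4 * grating_sf (sampling margin)",
         call. = FALSE)
  }
  p <- list(grating_sf = grating_sf, noise_contrast = noise_contrast,
            noise_smooth_sd = noise_smooth_sd,
            aperture_radius = aperture_radius,
            pixels_per_degree = pixels_per_degree,
            aperture_edge = aperture_edge)
  p$size_px <- as.integer(round(2 * aperture_radius * pixels_per_degree))
  class(p) <- "stimulus_params"
  p
}

#' Reduced-resolution stimulus parameters for batch processing
#'
#' Convenience constructor giving a `size_px` by `size_px` raster covering
#' the same 10-degree field (default 64 x 64, i.e. 6.4 pixels/degree).
#'
#' @param size_px raster side length in pixels.
#' @param ... passed to [stimulus_params()].
#' @return a `stimulus_params` list.
#' @export
reduced_stimulus_params <- function(size_px = 64L, ...) {
  args <- list(...)
  radius <- if (is.null(args$aperture_radius)) 5 else args$aperture_radius
  args$aperture_radius <- radius
  args$pixels_per_degree <- size_px / (2 * radius)
  do.call(stimulus_params, args)
}

# internal: pixel-center coordinate vectors in degrees (y increases upward)
raster_axes <- function(params) {
  n <- params$size_px
  half <- params$aperture_radius
  seq(-half, half, length.out = n + 1L)[-(n + 1L)] + half / n
}

# internal: raised-cosine circular aperture (1 inside, 0 outside)
aperture_window <- function(params) {
  ax <- raster_axes(params)
  r <- sqrt(outer(ax^2, ax^2, "+"))
  r0 <- params$aperture_radius
  w <- params$aperture_edge * r0
  a <- matrix(0, params$size_px, params$size_px)
  a[r <= r0 - w] <- 1
  ramp <- r > r0 - w & r < r0
  a[ramp] <- 0.5 * (1 + cos(pi * (r[ramp] - (r0 - w)) / w))
  a
}

# internal: sinusoidal carrier; orientation_deg measured clockwise from
# vertical, phase in cycles; quadrature = 0 gives sine, 0.25 cosine
grating_carrier <- function(orientation_deg, sf, params, phase = 0) {
  ax <- raster_axes(params)
  th <- orientation_deg * pi / 180
  # modulation axis is perpendicular to the stripes
  u <- outer(ax * (-sin(th)), ax * cos(th), "+") # rows = y, cols = x
  sin(2 * pi * (sf * u + phase))
}

#' Render a grating-in-noise stimulus image
#'
#' @param orientation `+1` (clockwise, +45 deg), `-1` (counterclockwise,
#'   -45 deg) or `0`/`NA` for no grating; ignored when `contrast` is 0.
#' @param contrast Michelson contrast of the grating component, in `[0, 1]`.
#' @param params a [stimulus_params()] list.
#' @param seed integer seed for the noise field and phase.
#' @param phase optional grating phase in cycles `[0, 1)`; drawn uniformly
#'   when `NULL`.
#' @return a `stimulus_image`: a luminance matrix in `[0, 1]` (background
#'   0.5) with the generating parameters attached as attributes.
#' @export
render_stimulus <- function(orientation, contrast, params = stimulus_params(),
                            seed = 1L, phase = NULL) {
  check_scalar(contrast, "contrast", lo = 0, hi = 1)
  set.seed(seed)
  if (is.null(phase)) phase <- stats::runif(1)
  n <- params$size_px
  ap <- aperture_window(params)

  signal <- 0
  if (contrast > 0 && !is.na(orientation) && orientation != 0) {
    carrier <- grating_carrier(orientation * 45, params$grating_sf, params,
                               phase = phase)
    signal <- 0.5 * contrast * carrier
  }

  noise <- matrix(stats::rnorm(n * n), n, n)
  sd_px <- params$noise_smooth_sd * params$pixels_per_degree
  noise <- gaussian_smooth(noise, sd_px)
  s <- stats::sd(as.vector(noise))
  if (s > 0 && params$noise_contrast > 0) {
    noise <- noise * (params$noise_contrast * 0.5 / s)
  } else {
    noise <- noise * 0
  }

  img <- 0.5 + ap * (signal + noise)
  img <- pmin(pmax(img, 0), 1)
  attr(img, "params") <- params
  attr(img, "orientation") <- if (contrast > 0) orientation else 0
  attr(img, "contrast") <- contrast
  attr(img, "phase") <- phase
  attr(img, "seed") <- seed
  class(img) <- c("stimulus_image", class(img))
  img
}

# internal: separable Gaussian smoothing via banded Toeplitz matrices
gaussian_smooth <- function(mat, sd_px) {
  if (sd_px <= 0) return(mat)
  n <- nrow(mat)
  half <- max(1L, ceiling(4 * sd_px))
  kern <- stats::dnorm(seq(-half, half), sd = sd_px)
  kern <- kern / sum(kern)
  d <- outer(seq_len(n), seq_len(n), "-")
  sm <- matrix(0, n, n)
  in_band <- abs(d) <= half
  sm[in_band] <- kern[d[in_band] + half + 1L]
  sm %*% mat %*% t(sm)
}

#' Build the quadrature Gabor filter bank
#'
#' 180 orientations (-89 to 90 degrees, step 1, positive = clockwise of
#' vertical) crossed with 9 spatial frequencies (0.6 to 1.4 cycles/degree,
#' step 0.1, the target frequency of 1 +/- 0.4). Each cell holds an even
#' (cosine) and an odd (sine) filter sharing a raised-cosine envelope
#' identical to the stimulus aperture; filters are DC-removed and normalized
#' to unit L2 norm so energies are comparable across cells.
#'
#' @param params a [stimulus_params()] list (sets the raster geometry).
#' @param orientations_deg orientation grid, degrees.
#' @param sfs_cpd spatial-frequency grid, cycles/degree.
#' @return a `filter_bank`: list with `even` and `odd` (cells x pixels
#'   matrices), `cells` (data.frame `orientation_deg`, `sf_cpd`), and the
#'   raster parameters.
#' @export
build_filter_bank <- function(params = stimulus_params(),
                              orientations_deg = seq(-89, 90),
                              sfs_cpd = seq(0.6, 1.4, by = 0.1)) {
  cells <- expand.grid(orientation_deg = orientations_deg, sf_cpd = sfs_cpd,
                       KEEP.OUT.ATTRS = FALSE)
  n_px <- params$size_px^2
  ap <- as.vector(aperture_window(params))
  even <- matrix(0, nrow(cells), n_px)
  odd <- matrix(0, nrow(cells), n_px)
  for (i in seq_len(nrow(cells))) {
    e <- ap * as.vector(grating_carrier(cells$orientation_deg[i],
                                        cells$sf_cpd[i], params,
                                        phase = 0.25)) # cosine
    o <- ap * as.vector(grating_carrier(cells$orientation_deg[i],
                                        cells$sf_cpd[i], params,
                                        phase = 0))    # sine
    e <- e - mean(e)
    o <- o - mean(o)
    even[i, ] <- e / sqrt(sum(e^2))
    odd[i, ] <- o / sqrt(sum(o^2))
  }
  structure(list(even = even, odd = odd, cells = cells, params = params),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("Gabor filter bank: %d orientations x %d spatial frequencies, %d px raster\n",
              length(unique(x$cells$orientation_deg)),
              length(unique(x$cells$sf_cpd)), x$params$size_px))
  invisible(x)
}

#' Orientation x spatial-frequency energy profile of one stimulus
#'
#' The energy in cell (o, f) is `sqrt(c^2 + s^2)` where `c` and `s` are the
#' inner products of the mean-subtracted raster with the even and odd Gabor
#' filters of the cell (quadrature pair), making the measure invariant to
#' grating phase.
#'
#' @param img a `stimulus_image`.
#' @param bank a [build_filter_bank()] result on the same raster.
#' @return an `energy_profile`: an orientations x frequencies matrix of
#'   nonnegative energies with the cell grid attached.
#' @export
compute_energy_profile <- function(img, bank) {
  p_img <- attr(img, "params")
  if (length(img) != ncol(bank$even)) {
    stop("raster resolution of image and filter bank differ", call. = FALSE)
  }
  if (!is.null(p_img) &&
      !isTRUE(all.equal(p_img$pixels_per_degree,
                        bank$params$pixels_per_degree))) {
    stop("pixels_per_degree of image and filter bank differ", call. = FALSE)
  }
  v <- as.vector(img) - mean(img)
  e <- sqrt((bank$even %*% v)^2 + (bank$odd %*% v)^2)
  ori <- sort(unique(bank$cells$orientation_deg))
  sfs <- sort(unique(bank$cells$sf_cpd))
  out <- matrix(NA_real_, length(ori), length(sfs),
                dimnames = list(orientation_deg = ori, sf_cpd = sfs))
  out[cbind(match(bank$cells$orientation_deg, ori),
            match(bank$cells$sf_cpd, sfs))] <- e
  structure(out, class = c("energy_profile", class(out)), cells = bank$cells)
}

#' Energy profiles for a batch of stimuli
#'
#' @param imgs list of `stimulus_image` objects on the bank's raster.
#' @param bank a [build_filter_bank()] result.
#' @return a trials x cells matrix of energies; the cell grid is attached as
#'   attribute `"cells"`.
#' @export
compute_energy_profiles <- function(imgs, bank) {
  stopifnot(length(imgs) >= 1L)
  v <- vapply(imgs, function(im) {
    if (length(im) != ncol(bank$even)) {
      stop("raster resolution of image and filter bank differ", call. = FALSE)
    }
    as.vector(im) - mean(im)
  }, numeric(ncol(bank$even)))
  e <- sqrt((bank$even %*% v)^2 + (bank$odd %*% v)^2)
  structure(t(e), cells = bank$cells)
}

#' Class-mean clockwise / counterclockwise energies
#'
#' Averages each trial's energies over the clockwise cells (orientations 1
#' to 89 degrees, all spatial frequencies) and counterclockwise cells (-89
#' to -1 degrees); 0 and 90 degrees belong to neither class.
#'
#' @param energy trials x cells matrix from [compute_energy_profiles()].
#' @param cells cell grid; defaults to the matrix's `"cells"` attribute.
#' @return a data.frame with columns `e_cw` and `e_ccw`, one row per trial.
#' @export
class_net_energies <- function(energy, cells = attr(energy, "cells")) {
  stopifnot(!is.null(cells), ncol(energy) == nrow(cells))
  cw <- cells$orientation_deg >= 1 & cells$orientation_deg <= 89
  ccw <- cells$orientation_deg <= -1 & cells$orientation_deg >= -89
  data.frame(e_cw = rowMeans(energy[, cw, drop = FALSE]),
             e_ccw = rowMeans(energy[, ccw, drop = FALSE]))
}
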