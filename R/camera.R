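#' Per-pixel sCMOS camera calibration
#'
#' Holds the three pre-calibrated per-pixel maps that define the sCMOS noise
#' model: dark offset (ADU), gain (ADU per photoelectron) and read-noise
#' variance (ADU^2). All localization fitting weights pixels by these maps.
#'
#' @param offset,gain,read_var numeric matrices of one common shape.
#' @return A `camera_calibration` object.
#' @export
camera_calibration <- function(offset, gain, read_var) {
  offset <- as.matrix(offset); gain <- as.matrix(gain)
  read_var <- as.matrix(read_var)
  if (!all(dim(offset) == dim(gain)) || !all(dim(offset) == dim(read_var)))
    stop("calibration maps must share one shape")
  if (any(gain <= 0)) stop("gain must be > 0 everywhere")
  if (any(read_var < 0)) stop("read-noise variance must be >= 0")
  structure(list(offset = offset, gain = gain, read_var = read_var),
            class = "camera_calibration")
}

#' Draw a synthetic sCMOS calibration
#'
#' Per-pixel offset, gain and read-noise sd are drawn from normal
#' distributions around typical sCMOS values.
#'
#' @param nrow,ncol sensor shape in pixels.
#' @param offset_mean,offset_sd dark offset (ADU), default 100 +/- 2.
#' @param gain_mean,gain_sd gain (ADU/e-), default 2.0 +/- 0.05.
#' @param read_sd_e read-noise sd in photoelectrons, default 1.5.
#' @param seed integer seed.
#' @return A [camera_calibration()].
#' @export
simulate_calibration <- function(nrow, ncol,
                                 offset_mean = 100, offset_sd = 2,
                                 gain_mean = 2, gain_sd = 0.05,
                                 read_sd_e = 1.5, seed = NULL) {
  with_seed(seed, {
    offset <- matrix(stats::rnorm(nrow * ncol, offset_mean, offset_sd), nrow)
    gain <- matrix(stats::rnorm(nrow * ncol, gain_mean, gain_sd), nrow)
    gain[gain < 0.1] <- 0.1
    read_var <- (read_sd_e * gain)^2   # ADU^2
    camera_calibration(offset, gain, read_var)
  })
}

#' Image stack
#'
#' @param frames 3D numeric array (frame, row, column) of ADU counts.
#' @param calibration a [camera_calibration()] matching the frame shape.
#' @param pixel_size_nm physical pixel size (nm).
#' @return An `image_stack` object.
#' @export
image_stack <- function(frames, calibration, pixel_size_nm = 100) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 1L)
    stop("`frames` must be a (frame, row, column) array with >= 1 frame")
  if (!all(dim(frames)[2:3] == dim(calibration$offset)))
    stop("frame shape does not match the calibration maps")
  stop_if_not_number(pixel_size_nm, "pixel_size_nm", positive = TRUE)
  structure(list(frames = frames, calibration = calibration,
                 pixel_size_nm = pixel_size_nm),
            class = "image_stack")
}

# Fraction of a unit-amplitude 2D Gaussian PSF centred at (x0, y0) (pixel
# units) integrated over each pixel of an nr x nc grid. Pixel (i, j) covers
# [i-1, i] x [j-1, j] in (row, col) coordinates.
psf_pixel_fractions <- function(x0, y0, sigma, nr, nc) {
  ex <- stats::pnorm(seq_len(nc), x0, sigma) -
    stats::pnorm(seq_len(nc) - 1, x0, sigma)
  ey <- stats::pnorm(seq_len(nr), y0, sigma) -
    stats::pnorm(seq_len(nr) - 1, y0, sigma)
  outer(ey, ex)   # rows = y, cols = x
}

#' Simulate raw sCMOS frames of point emitters
#'
#' Each pixel is `offset + gain * Poisson(mu) + N(0, read-noise sd)` where the
#' expected photoelectron count `mu` is the uniform background plus every
#' emitter's photon flux integrated over the pixel under a 2D Gaussian PSF.
#' This is the generative inverse of the localization likelihood used by
#' [localize_stack()].
#'
#' @param emitters data frame with columns `x`, `y` (pixel units, in
#'   `[0, ncol] x [0, nrow]`) and `photons`; may have zero rows.
#' @param calibration a [camera_calibration()].
#' @param psf_sigma PSF sd in pixels (> 0).
#' @param background uniform background (photons/pixel/frame).
#' @param n_frames number of frames.
#' @param pixel_size_nm physical pixel size (nm).
#' @param seed integer seed.
#' @return An [image_stack()].
#' @export
simulate_frames <- function(emitters, calibration, psf_sigma = 1.3,
                            background = 5, n_frames = 1,
                            pixel_size_nm = 100, seed = NULL) {
  stop_if_not_number(psf_sigma, "psf_sigma", positive = TRUE)
  stop_if_not_number(background, "background", nonneg = TRUE)
  nr <- nrow(calibration$offset); nc <- ncol(calibration$offset)
  if (nrow(emitters) > 0) {
    if (any(emitters$x < 0 | emitters$x > nc | emitters$y < 0 | emitters$y > nr))
      stop("emitter coordinates must lie inside the frame")
  }
  mu <- matrix(background, nr, nc)
  for (k in seq_len(nrow(emitters))) {
    mu <- mu + emitters$photons[k] *
      psf_pixel_fractions(emitters$x[k], emitters$y[k], psf_sigma, nr, nc)
  }
  with_seed(seed, {
    frames <- array(0, dim = c(n_frames, nr, nc))
    read_sd <- sqrt(calibration$read_var)
    for (f in seq_len(n_frames)) {
      shot <- matrix(stats::rpois(nr * nc, mu), nr, nc)
      frames[f, , ] <- calibration$offset + calibration$gain * shot +
        matrix(stats::rnorm(nr * nc, 0, read_sd), nr, nc)
    }
    image_stack(frames, calibration, pixel_size_nm)
  })
}
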