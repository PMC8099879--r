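#' @name localize
#' @title sCMOS maximum-likelihood single-emitter localization
#'
#' @description
#' [localize_stack()] turns a raw camera stack into a localization table.
#' Each frame is low-pass filtered with a box of 4x the PSF FWHM, weighting
#' every pixel by the inverse of its pre-calibrated variance; the low-pass
#' image is subtracted from the raw frame and local maxima above a noise
#' threshold become candidates. A 7 x 7 window around every candidate is fit
#' by maximum likelihood under the per-pixel sCMOS noise model (Poisson shot
#' noise convolved with Gaussian read noise, handled with the standard
#' variance-offset formulation), with free position, photon count and
#' background and the PSF sd fixed from the configured FWHM. The Fisher
#' information at the optimum gives the Cramer-Rao lower bound (CRLB) used as
#' the localization precision.
NULL

# Weighted box filter: moving average of `mat` with weights `w` over a
# k x k box (k odd), renormalized by the local weight sum.
box_filter_weighted <- function(mat, w, k) {
  stopifnot(k %% 2 == 1)
  boxsum <- function(m, k) {
    r <- (k - 1L) / 2L
    nr <- nrow(m); nc <- ncol(m)
    # cumulative-sum trick with zero padding
    cs <- matrix(0, nr + 2L * r + 1L, nc + 2L * r + 1L)
    cs[(r + 2L):(r + 1L + nr), (r + 2L):(r + 1L + nc)] <- m
    cs <- apply(apply(cs, 2L, cumsum), 1L, cumsum)  # transposed
    cs <- t(cs)
    i1 <- seq_len(nr); j1 <- seq_len(nc)
    cs[i1 + 2L * r + 1L, j1 + 2L * r + 1L, drop = FALSE] -
      cs[i1, j1 + 2L * r + 1L, drop = FALSE] -
      cs[i1 + 2L * r + 1L, j1, drop = FALSE] + cs[i1, j1, drop = FALSE]
  }
  boxsum(mat * w, k) / pmax(boxsum(w, k), .Machine$double.eps)
}

# 8-neighbour local maxima of `mat` above `thresh`, excluding a border of
# `margin` pixels. Returns a 2-column (row, col) matrix.
local_maxima <- function(mat, thresh, margin) {
  nr <- nrow(mat); nc <- ncol(mat)
  if (nr <= 2 * margin || nc <= 2 * margin) return(cbind(integer(0), integer(0)))
  best <- mat
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- matrix(-Inf, nr, nc)
    ri <- max(1, 1 + di):min(nr, nr + di)
    ci <- max(1, 1 + dj):min(nc, nc + dj)
    shifted[ri, ci] <- mat[ri - di, ci - dj]
    best <- pmax(best, shifted + 1e-12)
  }
  ok <- mat >= best & mat > thresh
  ok[c(seq_len(margin), nr - seq_len(margin) + 1L), ] <- FALSE
  ok[, c(seq_len(margin), nc - seq_len(margin) + 1L)] <- FALSE
  which(ok, arr.ind = TRUE)
}

# Negative log-likelihood and gradient of the sCMOS model on one window.
# z: photoelectron-converted data, v: read variance in e-^2 per pixel,
# theta = (x0, y0, N, b) in window pixel units / photons.
scmos_nll <- function(theta, z, v, sigma) {
  nr <- nrow(z); nc <- ncol(z)
  mu <- theta[4] + theta[3] *
    psf_pixel_fractions(theta[1], theta[2], sigma, nr, nc)
  m <- mu + v
  d <- z + v
  sum(m - d * log(pmax(m, 1e-12)))
}

scmos_grad <- function(theta, z, v, sigma) {
  nr <- nrow(z); nc <- ncol(z)
  x0 <- theta[1]; y0 <- theta[2]; N <- theta[3]
  ex <- stats::pnorm(seq_len(nc), x0, sigma) -
    stats::pnorm(seq_len(nc) - 1, x0, sigma)
  ey <- stats::pnorm(seq_len(nr), y0, sigma) -
    stats::pnorm(seq_len(nr) - 1, y0, sigma)
  dex <- (stats::dnorm(seq_len(nc) - 1, x0, sigma) -
            stats::dnorm(seq_len(nc), x0, sigma))
  dey <- (stats::dnorm(seq_len(nr) - 1, y0, sigma) -
            stats::dnorm(seq_len(nr), y0, sigma))
  E <- outer(ey, ex)
  mu <- theta[4] + N * E
  w <- 1 - (z + v) / pmax(mu + v, 1e-12)
  c(sum(w * N * outer(ey, dex)),
    sum(w * N * outer(dey, ex)),
    sum(w * E),
    sum(w))
}

# CRLB variances of (x0, y0, N, b) from the Fisher information at theta.
scmos_crlb <- function(theta, v, sigma, nr, nc) {
  x0 <- theta[1]; y0 <- theta[2]; N <- theta[3]
  ex <- stats::pnorm(seq_len(nc), x0, sigma) -
    stats::pnorm(seq_len(nc) - 1, x0, sigma)
  ey <- stats::pnorm(seq_len(nr), y0, sigma) -
    stats::pnorm(seq_len(nr) - 1, y0, sigma)
  dex <- (stats::dnorm(seq_len(nc) - 1, x0, sigma) -
            stats::dnorm(seq_len(nc), x0, sigma))
  dey <- (stats::dnorm(seq_len(nr) - 1, y0, sigma) -
            stats::dnorm(seq_len(nr), y0, sigma))
  mu <- theta[4] + N * outer(ey, ex)
  J <- list(N * outer(ey, dex), N * outer(dey, ex), outer(ey, ex),
            matrix(1, nr, nc))
  FI <- matrix(0, 4L, 4L)
  winv <- 1 / pmax(mu + v, 1e-12)
  for (a in 1:4) for (b in a:4) {
    FI[a, b] <- FI[b, a] <- sum(J[[a]] * J[[b]] * winv)
  }
  diag(tryCatch(solve(FI), error = function(e) matrix(NA_real_, 4L, 4L)))
}

#' Localize emitters in a raw image stack
#'
#' @param stack an [image_stack()].
#' @param psf_fwhm PSF full width at half maximum in pixels.
#' @param detection_threshold candidate threshold as a multiple of the robust
#'   noise sd of the band-passed frame (default 4).
#' @param photon_floor fitted localizations below this photon count are
#'   dropped (default 100).
#' @param max_deviance windows whose model deviance exceeds this value are
#'   rejected as crowded/multi-emitter; default the 0.9999 chi-square
#'   quantile at (49 - 4) degrees of freedom.
#' @return A localization table: data frame with columns `channel`, `x_nm`,
#'   `y_nm`, `frame`, `photons`, `background`, `precision_nm`, `crlb_x_nm2`,
#'   `crlb_y_nm2`, `multiplicity`.
#' @export
localize_stack <- function(stack, psf_fwhm = 3, detection_threshold = 4,
                           photon_floor = 100, max_deviance = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  stop_if_not_number(psf_fwhm, "psf_fwhm", positive = TRUE)
  cal <- stack$calibration
  nr <- nrow(cal$offset); nc <- ncol(cal$offset)
  sigma <- psf_fwhm / (2 * sqrt(2 * log(2)))
  box <- max(3L, 2L * floor(2 * psf_fwhm / 2) + 1L)  # ~4 x FWHM, odd
  wvar <- 1 / pmax(cal$read_var, .Machine$double.eps)
  v_e <- cal$read_var / cal$gain^2   # read variance in photoelectrons^2
  if (is.null(max_deviance)) max_deviance <- stats::qchisq(0.9999, 45)
  half <- 3L
  out <- list()
  for (f in seq_len(dim(stack$frames)[1])) {
    raw <- stack$frames[f, , ]
    lowpass <- box_filter_weighted(raw, wvar, box)
    diffim <- raw - lowpass
    noise_sd <- stats::mad(diffim)
    cand <- local_maxima(diffim, detection_threshold * noise_sd, half)
    for (k in seq_len(nrow(cand))) {
      i0 <- cand[k, 1]; j0 <- cand[k, 2]
      ri <- (i0 - half):(i0 + half); ci <- (j0 - half):(j0 + half)
      z <- (raw[ri, ci] - cal$offset[ri, ci]) / cal$gain[ri, ci]
      v <- v_e[ri, ci]
      b0 <- max(stats::median(z[c(1, 7), ]), 0.01)
      n0 <- max(sum(z) - 49 * b0, 50)
      th0 <- c(3.5, 3.5, n0, b0)
      fit <- tryCatch(
        stats::optim(th0, scmos_nll, gr = scmos_grad, z = z, v = v,
                     sigma = sigma, method = "L-BFGS-B",
                     lower = c(1.5, 1.5, 1, 0),
                     upper = c(5.5, 5.5, 1e7, max(max(z), 1)),
                     control = list(maxit = 100, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(fit) || fit$par[3] < photon_floor) next
      # deviance vs the saturated Poisson model (crowding / misfit check)
      mu <- fit$par[4] + fit$par[3] *
        psf_pixel_fractions(fit$par[1], fit$par[2], sigma, 7L, 7L)
      d <- pmax(z + v, 1e-12); m <- pmax(mu + v, 1e-12)
      dev <- 2 * sum(d * log(d / m) - (d - m))
      if (dev > max_deviance) next
      crlb <- scmos_crlb(fit$par, v, sigma, 7L, 7L)
      if (any(!is.finite(crlb[1:2])) || any(crlb[1:2] <= 0)) next
      px <- stack$pixel_size_nm
      out[[length(out) + 1L]] <- data.frame(
        channel = 1L,
        x_nm = (j0 - half - 1L + fit$par[1]) * px,
        y_nm = (i0 - half - 1L + fit$par[2]) * px,
        frame = f - 1L,
        photons = fit$par[3],
        background = fit$par[4],
        precision_nm = sqrt((crlb[1] + crlb[2]) / 2) * px,
        crlb_x_nm2 = crlb[1] * px^2,
        crlb_y_nm2 = crlb[2] * px^2,
        multiplicity = 1L
      )
    }
  }
  if (!length(out)) return(empty_localization_table())
  do.call(rbind, out)
}

empty_localization_table <- function() {
  data.frame(channel = integer(0), x_nm = numeric(0), y_nm = numeric(0),
             frame = integer(0), photons = numeric(0), background = numeric(0),
             precision_nm = numeric(0), crlb_x_nm2 = numeric(0),
             crlb_y_nm2 = numeric(0), multiplicity = integer(0))
}

#' Fit a skew-Gaussian distribution to localization precisions
#'
#' Maximum-likelihood fit of the skew-normal density
#' `2/omega * phi((x - xi)/omega) * Phi(alpha (x - xi)/omega)` to the
#' per-localization precision values, for quality-control reporting of a
#' dataset's precision distribution.
#'
#' @param precisions numeric vector of precision values (nm), or a
#'   localization table with a `precision_nm` column. At least 50 values.
#' @return List with `location`, `scale`, `shape`, `logLik`, `converged`.
#' @export
fit_precision_distribution <- function(precisions) {
  if (is.data.frame(precisions)) precisions <- precisions$precision_nm
  x <- precisions[is.finite(precisions)]
  if (length(x) < 50) stop("need at least 50 precision values")
  if (stats::sd(x) < .Machine$double.eps^0.5)
    stop("degenerate input: precision values are constant")
  # method-of-moments initialization from the sample skewness
  g1 <- mean((x - mean(x))^3) / stats::sd(x)^3
  g1 <- max(-0.95, min(0.95, g1)) * 0.9952  # clamp below the SN limit
  d <- sign(g1) * sqrt(pi / 2 * abs(g1)^(2 / 3) /
                         (abs(g1)^(2 / 3) + ((4 - pi) / 2)^(2 / 3)))
  a0 <- d / sqrt(max(1 - d^2, 1e-6))
  w0 <- stats::sd(x) / sqrt(max(1 - 2 * d^2 / pi, 0.1))
  xi0 <- mean(x) - w0 * d * sqrt(2 / pi)
  nll <- function(p) {
    z <- (x - p[1]) / p[2]
    -sum(log(2 / p[2]) + stats::dnorm(z, log = TRUE) +
           stats::pnorm(p[3] * z, log.p = TRUE))
  }
  fit <- stats::optim(c(xi0, w0, a0), nll, method = "L-BFGS-B",
                      lower = c(-Inf, 1e-6, -Inf),
                      control = list(maxit = 500))
  list(location = fit$par[1], scale = fit$par[2], shape = fit$par[3],
       logLik = -fit$value, converged = fit$convergence == 0)
}

#' Merge blinking events into single localizations
#'
#' Localizations that appear in consecutive frames within 2.5x the
#' localization precision of the running merged position are treated as one
#' blinking event of one fluorophore and collapsed to a single record at the
#' inverse-CRLB-variance-weighted mean position; the merged variance is
#' `1 / sum(1/var_i)` per axis, photons are summed and the chain length is
#' recorded as `multiplicity`.
#'
#' @param table a localization table (see [localize_stack()]).
#' @param gate gate in multiples of the candidate's precision (default 2.5).
#' @return A localization table with `sum(multiplicity)` equal to the input
#'   row count.
#' @export
merge_blinking <- function(table, gate = 2.5) {
  if (nrow(table) == 0) return(table)
  need <- c("x_nm", "y_nm", "frame", "precision_nm")
  if (!all(need %in% names(table))) stop("table lacks required columns")
  vx <- if ("crlb_x_nm2" %in% names(table)) table$crlb_x_nm2 else table$precision_nm^2
  vy <- if ("crlb_y_nm2" %in% names(table)) table$crlb_y_nm2 else table$precision_nm^2
  vx <- pmax(vx, 1e-9); vy <- pmax(vy, 1e-9)
  ord <- order(table$frame)
  table <- table[ord, , drop = FALSE]; vx <- vx[ord]; vy <- vy[ord]
  mult_in <- if ("multiplicity" %in% names(table)) table$multiplicity else rep(1L, nrow(table))
  photons <- if ("photons" %in% names(table)) table$photons else rep(NA_real_, nrow(table))

  chains <- list()   # each: list of accumulators
  active <- integer(0)  # indices into chains with last_frame == previous frame
  frames <- sort(unique(table$frame))
  for (f in frames) {
    active <- active[vapply(chains[active], function(ch) ch$last_frame == f - 1, TRUE)]
    rows <- which(table$frame == f)
    used <- rep(FALSE, length(active))
    for (r in rows) {
      px <- table$x_nm[r]; py <- table$y_nm[r]
      gate_nm <- gate * table$precision_nm[r]
      best <- 0L; bestd <- Inf
      for (ai in seq_along(active)) {
        if (used[ai]) next
        ch <- chains[[active[ai]]]
        if (ch$last_frame != f - 1) next  # same-frame records never chain
        dx <- ch$wx / ch$swx - px; dy <- ch$wy / ch$swy - py
        d <- sqrt(dx * dx + dy * dy)
        if (is.finite(gate_nm) && d <= gate_nm && d < bestd) {
          best <- ai; bestd <- d
        }
      }
      if (best > 0L) {
        ci <- active[best]
        chains[[ci]]$wx <- chains[[ci]]$wx + px / vx[r]
        chains[[ci]]$swx <- chains[[ci]]$swx + 1 / vx[r]
        chains[[ci]]$wy <- chains[[ci]]$wy + py / vy[r]
        chains[[ci]]$swy <- chains[[ci]]$swy + 1 / vy[r]
        chains[[ci]]$photons <- chains[[ci]]$photons + photons[r]
        chains[[ci]]$mult <- chains[[ci]]$mult + mult_in[r]
        chains[[ci]]$last_frame <- f
        used[best] <- TRUE
      } else {
        chains[[length(chains) + 1L]] <- list(
          wx = px / vx[r], swx = 1 / vx[r], wy = py / vy[r], swy = 1 / vy[r],
          photons = photons[r], mult = mult_in[r],
          first_frame = f, last_frame = f, proto = r)
        used <- c(used, FALSE)
        active <- c(active, length(chains))
      }
    }
  }
  res <- lapply(chains, function(ch) {
    row <- table[ch$proto, , drop = FALSE]
    row$x_nm <- ch$wx / ch$swx
    row$y_nm <- ch$wy / ch$swy
    row$frame <- ch$first_frame
    if ("photons" %in% names(row)) row$photons <- ch$photons
    row$crlb_x_nm2 <- 1 / ch$swx
    row$crlb_y_nm2 <- 1 / ch$swy
    row$precision_nm <- sqrt((1 / ch$swx + 1 / ch$swy) / 2)
    row$multiplicity <- ch$mult
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$frame), , drop = FALSE]
}

#' Render a localization field to a Gaussian-smoothed canvas
#'
#' Coordinates are histogrammed on a `pixel_size` canvas and convolved with a
#' normalized 2D Gaussian kernel; total mass equals the record count up to
#' truncation at the canvas boundary.
#'
#' @param field a [localization_field()] or any data frame with
#'   `x_nm`/`y_nm`.
#' @param pixel_size canvas pixel size (nm), default 10.
#' @param kernel_sigma Gaussian kernel sd (nm), default 10.
#' @return Numeric matrix (rows = y, cols = x).
#' @export
render_image <- function(field, pixel_size = 10, kernel_sigma = 10) {
  stop_if_not_number(pixel_size, "pixel_size", positive = TRUE)
  stop_if_not_number(kernel_sigma, "kernel_sigma", positive = TRUE)
  roi <- attr(field, "roi")
  if (is.null(roi)) {
    if (nrow(field) == 0) return(matrix(0, 1, 1))
    roi <- c(min(field$x_nm), max(field$x_nm) + pixel_size,
             min(field$y_nm), max(field$y_nm) + pixel_size)
  }
  nc <- max(1L, ceiling((roi[2] - roi[1]) / pixel_size))
  nr <- max(1L, ceiling((roi[4] - roi[3]) / pixel_size))
  img <- matrix(0, nr, nc)
  if (nrow(field)) {
    jx <- pmin(pmax(floor((field$x_nm - roi[1]) / pixel_size) + 1L, 1L), nc)
    iy <- pmin(pmax(floor((field$y_nm - roi[3]) / pixel_size) + 1L, 1L), nr)
    counts <- table(factor(iy + (jx - 1L) * nr, levels = seq_len(nr * nc)))
    img <- matrix(as.numeric(counts), nr, nc)
  }
  rad <- ceiling(5 * kernel_sigma / pixel_size)
  k <- stats::dnorm(seq(-rad, rad) * pixel_size, 0, kernel_sigma)
  k <- k / sum(k)
  conv1 <- function(m, k) {   # along rows (first margin), zero-padded
    r <- (length(k) - 1L) / 2L
    out <- matrix(0, nrow(m), ncol(m))
    for (o in -r:r) {
      src <- max(1, 1 - o):min(nrow(m), nrow(m) - o)
      out[src + o, ] <- out[src + o, ] + k[o + r + 1L] * m[src, ]
    }
    out
  }
  t(conv1(t(conv1(img, k)), k))
}
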