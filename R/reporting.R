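#' Per-condition summary of scene-level values
#'
#' @param values numeric vector of per-scene (per-nucleus) values.
#' @param label condition label.
#' @return A `group_summary`: `label`, `values`, `mean`, `sd`, `sem`, `n`
#'   with `sem = sd/sqrt(n)`.
#' @export
group_summary <- function(values, label = "") {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  n <- length(values)
  s <- if (n > 1) stats::sd(values) else 0
  structure(list(label = label, values = values, mean = mean(values),
                 sd = s, sem = s / sqrt(n), n = n),
            class = "group_summary")
}

#' Percent change between two condition summaries with propagated s.e.m.
#'
#' `pct = 100 (m_t - m_r) / m_r`; the uncertainty is propagated to first
#' order from the two independent group means:
#' `sem_pct = 100 (m_t/m_r) sqrt((s_r/m_r)^2 + (s_t/m_t)^2)` with `s` the
#' group s.e.m.s.
#'
#' @param reference,treated `group_summary` objects (or numeric vectors).
#' @return List with `percent_change` and `sem`.
#' @export
percent_change <- function(reference, treated) {
  if (!inherits(reference, "group_summary")) reference <- group_summary(reference)
  if (!inherits(treated, "group_summary")) treated <- group_summary(treated)
  mr <- reference$mean; mt <- treated$mean
  if (mr == 0) stop("reference mean is zero; percent change undefined")
  pct <- 100 * (mt - mr) / mr
  sem <- if (mt == 0) 100 * reference$sem / abs(mr) else
    100 * abs(mt / mr) * sqrt((reference$sem / mr)^2 + (treated$sem / mt)^2)
  list(percent_change = pct, sem = sem)
}

#' Unpaired two-sample t-test
#'
#' Welch's unequal-variance test by default (`var_equal = TRUE` for the
#' pooled-variance variant). Groups with zero variance are handled with a
#' small-variance floor so the statistic stays finite: identical groups give
#' `t = 0, p = 1`, constant groups with different means give a very large
#' finite `t`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param var_equal pool the variances? default `FALSE` (Welch).
#' @return List with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b, var_equal = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: floor the standard error at sqrt(eps) x scale
    scale <- max(abs(c(a, b)), 1)
    se <- sqrt(.Machine$double.eps) * scale
    tval <- (mean(a) - mean(b)) / se
    df <- length(a) + length(b) - 2
    return(list(t = tval, p = 2 * stats::pt(-abs(tval), df), df = df,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

loc_required_cols <- c("channel", "x_nm", "y_nm", "frame", "photons",
                       "precision_nm")

#' Read / write localization tables
#'
#' Comma-separated, UTF-8, dot-decimal CSV with a mandatory header carrying
#' at least `channel, x_nm, y_nm, frame, photons, precision_nm`; unknown
#' extra columns are preserved, and a write/read round trip is lossless.
#'
#' @param path file path.
#' @return `read_localizations` returns the localization data frame.
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(loc_required_cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  for (col in c("x_nm", "y_nm", "photons", "precision_nm")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad))
        stop(sprintf("non-numeric value in column '%s' at data row %d",
                     col, bad[1]))
      df[[col]] <- as.numeric(v)
    }
  }
  df
}

#' @param table localization data frame (must contain the required columns).
#' @rdname read_localizations
#' @export
write_localizations <- function(table, path) {
  missing <- setdiff(loc_required_cols, names(table))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read / write FRET trajectory tables
#'
#' CSV with columns `frame`, `donor`, `acceptor`.
#' @param path file path.
#' @return `read_fret_trajectory` returns a data frame.
#' @export
read_fret_trajectory <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame", "donor", "acceptor")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df
}

#' @param traj data frame with `frame`, `donor`, `acceptor`.
#' @rdname read_fret_trajectory
#' @export
write_fret_trajectory <- function(traj, path) {
  utils::write.csv(traj[, c("frame", "donor", "acceptor")], path,
                   row.names = FALSE)
  invisible(path)
}

tiff_scale <- 65535   # ADU values stored as 32-bit float fractions of 2^16-1

#' Write / read an image stack as multi-frame TIFF
#'
#' Frames are stored as 32-bit float TIFF pages, scaled from ADU by
#' 1/65535 (the TIFF library's unit range); [read_image_stack()] restores
#' ADU. The calibration is not embedded (keep it as its own three-page TIFF
#' written with [write_calibration()]).
#'
#' @param stack an [image_stack()].
#' @param path file path.
#' @export
write_image_stack <- function(stack, path) {
  frames <- lapply(seq_len(dim(stack$frames)[1]),
                   function(f) stack$frames[f, , ] / tiff_scale)
  if (any(vapply(frames, function(m) any(m < 0 | m > 1), TRUE)))
    stop("ADU values outside [0, 65535] cannot be stored")
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @param calibration a [camera_calibration()] for reassembling the stack.
#' @param pixel_size_nm pixel size of the returned stack (nm).
#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, calibration, pixel_size_nm = 100) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (f in seq_along(pages)) arr[f, , ] <- pages[[f]] * tiff_scale
  image_stack(arr, calibration, pixel_size_nm)
}

#' Write / read a camera calibration as a three-page TIFF
#'
#' Pages are offset (ADU), gain (ADU/e-) and read-noise variance (ADU^2).
#' @param calibration a [camera_calibration()].
#' @param path file path.
#' @export
write_calibration <- function(calibration, path) {
  tiff::writeTIFF(list(calibration$offset / tiff_scale,
                       calibration$gain / tiff_scale,
                       calibration$read_var / tiff_scale),
                  path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) stop("calibration TIFF must have 3 pages")
  camera_calibration(pages[[1]] * tiff_scale, pages[[2]] * tiff_scale,
                     pages[[3]] * tiff_scale)
}

#' Write a correlation profile or TC map to CSV
#'
#' @param x a `correlation_profile` or `tc_map`.
#' @param path file path.
#' @export
write_profile <- function(x, path) {
  if (inherits(x, "tc_map")) {
    idx <- which(x$n_shift > 0, arr.ind = TRUE)
    df <- data.frame(r1_nm = x$r_centers[idx[, 1]],
                     r2_nm = x$r_centers[idx[, 2]],
                     r3_nm = x$r3_centers[idx[, 3]],
                     f = x$f[idx], support = x$support[idx],
                     n_shift = x$n_shift[idx])
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
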