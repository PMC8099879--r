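#' Pair-correlation statistics of SMLM fields
#'
#' @description
#' [auto_correlation()] computes the radial pair-correlation g(r) of one
#' field; [cross_correlation()] the two-channel analogue c(r). Both use the
#' un-centred normalization `<rho rho> / <rho>^2`, whose value under complete
#' spatial randomness (CSR) / independence is 1 — the baseline the
#' two-Gaussian focus model carries as its "+1" term. Reference points are
#' restricted to the ROI eroded by `r_max` so annulus areas need no boundary
#' correction; densities are taken from the full ROI.
#'
#' @name pair-correlation
NULL

erode_indices <- function(field, r_max) {
  roi <- roi_of(field)
  which(field$x_nm >= roi[1] + r_max & field$x_nm <= roi[2] - r_max &
          field$y_nm >= roi[3] + r_max & field$y_nm <= roi[4] - r_max)
}

correlation_profile <- function(r_edges, value, pairs, type) {
  df <- data.frame(r_nm = (r_edges[-1] + r_edges[-length(r_edges)]) / 2,
                   value = value, pairs = pairs)
  attr(df, "bin_width") <- diff(r_edges)[1]
  attr(df, "type") <- type
  class(df) <- c("correlation_profile", "data.frame")
  df
}

# Shared annulus-count engine: counts neighbours of `ref` points (rows of a
# 2-col matrix) among `pts` in distance bins r_edges.
radial_pair_counts <- function(ref, pts, r_edges) {
  nb <- length(r_edges) - 1L
  counts <- numeric(nb)
  if (nrow(ref) == 0 || nrow(pts) == 0) return(counts)
  r_max <- r_edges[length(r_edges)]
  for (i in seq_len(nrow(ref))) {
    dx <- pts[, 1] - ref[i, 1]; dy <- pts[, 2] - ref[i, 2]
    d2 <- dx * dx + dy * dy
    d <- sqrt(d2[d2 <= r_max^2])
    counts <- counts + tabulate(findInterval(d, r_edges), nbins = nb)
  }
  counts
}

#' Auto pair-correlation g(r)
#'
#' @param field a [localization_field()] with at least 2 points.
#' @param bin_width radial bin width (nm), default 10.
#' @param r_max maximum distance (nm), default 500; must be below half the
#'   ROI side.
#' @return A `correlation_profile` data frame (`r_nm`, `value`, `pairs`).
#' @export
auto_correlation <- function(field, bin_width = 10, r_max = 500) {
  stop_if_not_number(bin_width, "bin_width", positive = TRUE)
  stop_if_not_number(r_max, "r_max", positive = TRUE)
  roi <- roi_of(field)
  if (r_max >= min(roi[2] - roi[1], roi[4] - roi[3]) / 2)
    stop("r_max must be below half the ROI side")
  if (nrow(field) < 2) stop("need at least 2 points")
  ref_idx <- erode_indices(field, r_max)
  r_edges <- seq(0, r_max, by = bin_width)
  pts <- cbind(field$x_nm, field$y_nm)
  counts <- numeric(length(r_edges) - 1L)
  for (i in ref_idx) {
    dx <- pts[, 1] - pts[i, 1]; dy <- pts[, 2] - pts[i, 2]
    d2 <- dx * dx + dy * dy
    d <- sqrt(d2[d2 <= r_max^2 & seq_len(nrow(pts)) != i])
    counts <- counts + tabulate(findInterval(d, r_edges),
                                nbins = length(r_edges) - 1L)
  }
  rho <- nrow(field) / ((roi[2] - roi[1]) * (roi[4] - roi[3]))  # per nm^2
  areas <- pi * diff(r_edges^2)
  g <- counts / (max(length(ref_idx), 1L) * areas * rho)
  correlation_profile(r_edges, g, counts, "auto")
}

#' Cross pair-correlation c(r) between two channels
#'
#' Computes the inter-channel pair correlation of `fieldA` (reference) and
#' `fieldB`; independence gives c(r) = 1. If a `null` field is supplied
#' (e.g. channel B from a different nucleus), the same statistic computed
#' against it is returned as the randomized baseline; otherwise a toroidally
#' shifted copy of `fieldB` is used.
#'
#' @param fieldA,fieldB registered [localization_field()]s on one ROI.
#' @param bin_width,r_max as in [auto_correlation()].
#' @param null optional unrelated field for the baseline; `NULL` for a
#'   toroidal shift; `NA` to skip the baseline.
#' @param seed seed for the toroidal shift.
#' @return A `correlation_profile`; the baseline profile is attached as
#'   attribute `"null_profile"`.
#' @export
cross_correlation <- function(fieldA, fieldB, bin_width = 10, r_max = 500,
                              null = NULL, seed = NULL) {
  roiA <- roi_of(fieldA); roiB <- roi_of(fieldB)
  if (any(abs(roiA - roiB) > 1e-6)) stop("fields must share one ROI")
  if (r_max >= min(roiA[2] - roiA[1], roiA[4] - roiA[3]) / 2)
    stop("r_max must be below half the ROI side")
  cross_one <- function(fb) {
    ref_idx <- erode_indices(fieldA, r_max)
    r_edges <- seq(0, r_max, by = bin_width)
    counts <- radial_pair_counts(
      cbind(fieldA$x_nm, fieldA$y_nm)[ref_idx, , drop = FALSE],
      cbind(fb$x_nm, fb$y_nm), r_edges)
    rhoB <- nrow(fb) / ((roiA[2] - roiA[1]) * (roiA[4] - roiA[3]))
    areas <- pi * diff(r_edges^2)
    correlation_profile(r_edges,
                        counts / (max(length(ref_idx), 1L) * areas * rhoB),
                        counts, "cross")
  }
  prof <- cross_one(fieldB)
  if (!(length(null) == 1L && is.na(null))) {
    nullB <- if (is.null(null)) toroidal_shift(fieldB, seed = seed) else null
    attr(prof, "null_profile") <- cross_one(nullB)
  }
  prof
}

# Toroidal (wrap-around) random shift of a field within its ROI.
toroidal_shift <- function(field, seed = NULL) {
  roi <- roi_of(field)
  w <- roi[2] - roi[1]; h <- roi[4] - roi[3]
  with_seed(seed, {
    dx <- stats::runif(1, 0, w); dy <- stats::runif(1, 0, h)
    field$x_nm <- roi[1] + (field$x_nm - roi[1] + dx) %% w
    field$y_nm <- roi[3] + (field$y_nm - roi[3] + dy) %% h
    field
  })
}

#' Fit the two-Gaussian focus model to a g(r) profile
#'
#' Weighted least-squares fit of
#' `g(r) = exp(-r^2/(4 sigma^2)) / (4 pi sigma^2 rho) +
#'         A exp(-r^2 / (4 (sigma^2 + r_app^2))) + 1`,
#' where `sigma` is the localization precision, `rho` the fixed global
#' density, `A` the clustering amplitude and `r_app` the apparent (sigma)
#' radius of the Gaussian-modelled focus. The average molecular content per
#' focus is `N = 2 pi rho A r_app^2`. Bin weights are `1/sqrt(pairs + 1)`
#' and the first bin (self/merge artefacts) is excluded.
#'
#' @param profile a `correlation_profile` from [auto_correlation()] with at
#'   least 10 bins.
#' @param rho global density in points per square micrometre (> 0).
#' @return An `ac_fit` list: `sigma_nm`, `A`, `r_app_nm`, `N`, `rho_um2`,
#'   `cov` (fit covariance), `flags`.
#' @export
fit_ac_model <- function(profile, rho) {
  stop_if_not_number(rho, "rho", positive = TRUE)
  if (nrow(profile) < 10) stop("profile needs >= 10 bins")
  rho_nm <- rho / 1e6
  dat <- profile[-1L, , drop = FALSE]   # drop self-pair bin
  w <- 1 / sqrt(dat$pairs + 1)
  start <- list(sigma = 15,
                A = max(max(dat$value) - 1, 0.1),
                r_app = max(dat$r_nm[which.min(abs(dat$value - 1 -
                  (max(dat$value) - 1) / 2))], 20))
  do_fit <- function(st) minpack.lm::nlsLM(
    value ~ exp(-r_nm^2 / (4 * sigma^2)) / (4 * pi * sigma^2 * rho_nm) +
      A * exp(-r_nm^2 / (4 * (sigma^2 + r_app^2))) + 1,
    data = dat, start = st, weights = w,
    lower = c(sigma = 1, A = 0, r_app = 1),
    upper = c(sigma = 200, A = 1e6, r_app = 1e4),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  fit <- tryCatch(do_fit(start), error = function(e)
    tryCatch(do_fit(list(sigma = 15, A = 0.5, r_app = 75)),
             error = function(e2) NULL))
  if (is.null(fit)) {
    # flat profile (no clustering signal): the amplitude is indistinguishable
    # from zero and the model degenerates; report A = 0 with a flag
    noise <- 3 / sqrt(max(min(dat$pairs), 1))
    if (max(dat$value) < 1 + max(3 * noise, 0.5)) {
      return(structure(list(
        sigma_nm = NA_real_, A = 0, r_app_nm = NA_real_, N = 0,
        rho_um2 = rho, cov = NULL,
        flags = c("amplitude_clipped_at_zero", "flat_profile"), fit = NULL
      ), class = "ac_fit"))
    }
    stop("two-Gaussian fit failed to converge")
  }
  p <- stats::coef(fit)
  flags <- character(0)
  if (p[["A"]] <= 1e-8) flags <- c(flags, "amplitude_clipped_at_zero")
  structure(list(
    sigma_nm = p[["sigma"]], A = p[["A"]], r_app_nm = p[["r_app"]],
    N = 2 * pi * rho_nm * p[["A"]] * p[["r_app"]]^2,
    rho_um2 = rho, cov = stats::vcov(fit), flags = flags, fit = fit
  ), class = "ac_fit")
}

#' @export
print.ac_fit <- function(x, ...) {
  cat(sprintf(
    "<ac_fit> sigma = %.1f nm, A = %.3g, r_app = %.1f nm, <N> = %.3g (rho = %.3g /um^2)%s\n",
    x$sigma_nm, x$A, x$r_app_nm, x$N, x$rho_um2,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}
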