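#' Localization field
#'
#' A `localization_field` is the working container for one colour channel of
#' one region of interest (ROI): a data frame of molecular coordinates in
#' nanometres with an attached rectangular ROI. All correlation and
#' colocalization statistics in this package consume fields.
#'
#' @param x,y numeric vectors of coordinates (nm).
#' @param roi numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in nm.
#' @param precision_nm optional per-point localization precision (nm);
#'   recycled if length 1.
#' @param channel channel identifier (scalar or vector).
#'
#' @return A data frame of class `localization_field` with columns `x_nm`,
#'   `y_nm`, `precision_nm`, `channel` and attribute `roi`.
#' @export
localization_field <- function(x, y, roi,
                               precision_nm = NA_real_, channel = 1L) {
  stopifnot(length(x) == length(y))
  if (length(roi) != 4L || roi[2] <= roi[1] || roi[4] <= roi[3])
    stop("`roi` must be c(xmin, xmax, ymin, ymax) with positive extent")
  if (length(x)) {
    inside <- x >= roi[1] & x <= roi[2] & y >= roi[3] & y <= roi[4]
    if (!all(inside))
      stop(sprintf("%d point(s) fall outside the ROI", sum(!inside)))
  }
  df <- data.frame(
    x_nm = as.numeric(x), y_nm = as.numeric(y),
    precision_nm = rep_len(as.numeric(precision_nm), length(x)),
    channel = rep_len(channel, length(x))
  )
  attr(df, "roi") <- as.numeric(roi)
  class(df) <- c("localization_field", "data.frame")
  df
}

#' @export
print.localization_field <- function(x, ...) {
  roi <- attr(x, "roi")
  cat(sprintf(
    "<localization_field> %d points, ROI [%.0f, %.0f] x [%.0f, %.0f] nm (%.2f um^2)\n",
    nrow(x), roi[1], roi[2], roi[3], roi[4], roi_area_um2(x)))
  invisible(x)
}

roi_of <- function(field) {
  roi <- attr(field, "roi")
  if (is.null(roi)) stop("field has no ROI attribute")
  roi
}

roi_area_um2 <- function(field) {
  roi <- roi_of(field)
  (roi[2] - roi[1]) * (roi[4] - roi[3]) / 1e6
}

#' Global point density of a field
#'
#' @param field a [localization_field()].
#' @return Density in points per square micrometre.
#' @export
field_density <- function(field) nrow(field) / roi_area_um2(field)

#' Crop a localization table to a centred square ROI
#'
#' Retains the points inside a square of side `side` centred at `center` —
#' the standard preprocessing step before nucleus-level correlation analysis
#' (default 6 x 6 um, matching a central nuclear region).
#'
#' @param table a data frame with `x_nm`, `y_nm` columns (e.g. a localization
#'   table or field).
#' @param side square side (nm).
#' @param center numeric length-2 `c(x, y)` centre (nm); defaults to the
#'   midpoint of the data's bounding box.
#' @param channel channel id recorded on the result (defaults to the table's
#'   `channel` column if present).
#' @return A [localization_field()] whose ROI is the crop square. An empty
#'   result is allowed and flagged with a warning.
#' @export
crop_roi <- function(table, side = 6000, center = NULL, channel = NULL) {
  stop_if_not_number(side, "side", positive = TRUE)
  if (is.null(center)) {
    center <- c(mean(range(table$x_nm)), mean(range(table$y_nm)))
  }
  half <- side / 2
  roi <- c(center[1] - half, center[1] + half, center[2] - half, center[2] + half)
  keep <- table$x_nm >= roi[1] & table$x_nm <= roi[2] &
    table$y_nm >= roi[3] & table$y_nm <= roi[4]
  if (!any(keep)) warning("crop_roi: no points inside the ROI")
  prec <- if ("precision_nm" %in% names(table)) table$precision_nm[keep] else NA_real_
  chan <- channel %||% (if ("channel" %in% names(table)) table$channel[keep] else 1L)
  localization_field(table$x_nm[keep], table$y_nm[keep], roi,
                     precision_nm = prec, channel = chan)
}

#' Simulate a completely spatially random (CSR) field
#'
#' Homogeneous Poisson point process on a square ROI; the null model for all
#' correlation statistics.
#'
#' @param density intensity in points per square micrometre (>= 0).
#' @param roi_size square ROI side (nm).
#' @param seed integer seed (optional).
#' @param channel channel id.
#' @return A [localization_field()].
#' @export
generate_point_field <- function(density, roi_size = 6000, seed = NULL,
                                 channel = 1L) {
  stop_if_not_number(density, "density", nonneg = TRUE)
  stop_if_not_number(roi_size, "roi_size", positive = TRUE)
  with_seed(seed, {
    area_um2 <- (roi_size / 1000)^2
    n <- stats::rpois(1L, density * area_um2)
    localization_field(stats::runif(n, 0, roi_size), stats::runif(n, 0, roi_size),
                       roi = c(0, roi_size, 0, roi_size), channel = channel)
  })
}

#' Simulate a clustered localization field for pair-correlation analysis
#'
#' Plants `n_clusters` Gaussian foci (molecular scatter sd `r_app`) in the
#' ROI. Each focus draws Poisson-distributed molecules, each molecule is
#' observed `1 + Poisson(mu_blink)` times (residual blinking after merge),
#' and every localization is jittered by the localization precision. The
#' `content` parameter is the focus's apparent molecular content in the
#' pair-correlation sense, i.e. the quantity `N = 2 pi rho A r_app^2`
#' recovered by [fit_ac_model()]: it equals half the mean number of
#' localization pairs per focus member, so the planted mean molecule count
#' per focus is `2 * content / (1 + mu_blink)`. The default
#' `mu_blink = 0.62` makes the self-pair statistics consistent with the
#' model's single-molecule term (`E[m(m-1)] = E[m]`).
#'
#' @param n_clusters number of foci.
#' @param content apparent molecular content per focus (see above).
#' @param r_app focus Gaussian radius (sd, nm).
#' @param precision localization precision sd (nm).
#' @param roi_size ROI side (nm).
#' @param background_density CSR background (points/um^2).
#' @param mu_blink mean extra localizations per molecule.
#' @param seed integer seed.
#' @return A [localization_field()]; attribute `"truth"` records the
#'   planted parameters.
#' @export
generate_clustered_field <- function(n_clusters = 150, content = 20,
                                     r_app = 50, precision = 10,
                                     roi_size = 6000, background_density = 0,
                                     mu_blink = 0.62, seed = NULL) {
  stop_if_not_number(content, "content", positive = TRUE)
  stop_if_not_number(r_app, "r_app", positive = TRUE)
  lambda <- 2 * content / (1 + mu_blink)
  with_seed(seed, {
    L <- roi_size
    margin <- min(4 * (r_app + precision), L / 4)
    cx <- stats::runif(n_clusters, margin, L - margin)
    cy <- stats::runif(n_clusters, margin, L - margin)
    xs <- ys <- numeric(0)
    for (i in seq_len(n_clusters)) {
      nmol <- stats::rpois(1L, lambda)
      if (nmol == 0) next
      mx <- cx[i] + stats::rnorm(nmol, 0, r_app)
      my <- cy[i] + stats::rnorm(nmol, 0, r_app)
      reps <- 1L + stats::rpois(nmol, mu_blink)
      mx <- rep(mx, reps); my <- rep(my, reps)
      xs <- c(xs, mx + stats::rnorm(length(mx), 0, precision))
      ys <- c(ys, my + stats::rnorm(length(my), 0, precision))
    }
    nbg <- stats::rpois(1L, background_density * (L / 1000)^2)
    xs <- c(xs, stats::runif(nbg, 0, L)); ys <- c(ys, stats::runif(nbg, 0, L))
    keep <- xs >= 0 & xs <= L & ys >= 0 & ys <= L
    fld <- localization_field(xs[keep], ys[keep], roi = c(0, L, 0, L),
                              precision_nm = precision)
    attr(fld, "truth") <- list(n_clusters = n_clusters, content = content,
                               r_app = r_app, precision = precision,
                               lambda = lambda, mu_blink = mu_blink)
    fld
  })
}

#' Specification of a synthetic three-channel triplet scene
#'
#' Describes a nuclear-scale SMLM scene in which `n_triplets` three-species
#' site triplets of fixed pairwise geometry are planted on a CSR background.
#' The geometry `triplet_geometry = c(r12, r13, r23)` gives the distances
#' channel1-channel2, channel1-channel3 and channel2-channel3 in nm and must
#' satisfy the triangle inequality. Each vertex is dressed with a Poisson
#' number of molecules (mean `molecules_per_site` per channel) scattered with
#' sd `site_sigma`, thinned by `detection_efficiency` and jittered by the
#' localization error `localization_sigma`.
#'
#' @param roi_size ROI side (nm).
#' @param background_density length-3 CSR background density per channel
#'   (points/um^2).
#' @param n_triplets number of planted triplets.
#' @param triplet_geometry length-3 pairwise distances (nm): 1-2, 1-3, 2-3.
#' @param molecules_per_site length-3 mean molecules per site per channel.
#' @param site_sigma molecular scatter about each site (nm).
#' @param detection_efficiency length-3 per-channel detection probability.
#' @param localization_sigma localization error sd (nm).
#' @param seed integer seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(roi_size = 6000,
                       background_density = c(20, 20, 20),
                       n_triplets = 50,
                       triplet_geometry = c(100, 100, 100),
                       molecules_per_site = c(8, 8, 8),
                       site_sigma = 15,
                       detection_efficiency = c(0.8, 0.8, 0.8),
                       localization_sigma = 10,
                       seed = NULL) {
  background_density <- rep_len(background_density, 3L)
  molecules_per_site <- rep_len(molecules_per_site, 3L)
  detection_efficiency <- rep_len(detection_efficiency, 3L)
  if (any(background_density < 0) || any(molecules_per_site < 0))
    stop("densities and molecule counts must be >= 0")
  if (any(detection_efficiency < 0 | detection_efficiency > 1))
    stop("detection_efficiency must lie in [0, 1]")
  g <- triplet_geometry
  if (length(g) != 3L || any(g <= 0) ||
      g[1] + g[2] < g[3] || g[1] + g[3] < g[2] || g[2] + g[3] < g[1])
    stop("triplet_geometry must satisfy the triangle inequality")
  stop_if_not_number(site_sigma, "site_sigma", nonneg = TRUE)
  stop_if_not_number(localization_sigma, "localization_sigma", nonneg = TRUE)
  structure(list(
    roi_size = roi_size, background_density = background_density,
    n_triplets = as.integer(n_triplets), triplet_geometry = g,
    molecules_per_site = molecules_per_site, site_sigma = site_sigma,
    detection_efficiency = detection_efficiency,
    localization_sigma = localization_sigma, seed = seed
  ), class = "scene_spec")
}

# Vertex offsets of a triangle with side lengths r12, r13, r23, vertex 1 at
# the origin and vertex 2 on the +x axis.
triangle_vertices <- function(g) {
  r12 <- g[1]; r13 <- g[2]; r23 <- g[3]
  cosa <- (r12^2 + r13^2 - r23^2) / (2 * r12 * r13)
  cosa <- max(-1, min(1, cosa))
  sina <- sqrt(1 - cosa^2)
  rbind(c(0, 0), c(r12, 0), c(r13 * cosa, r13 * sina))
}

#' Generate a three-channel scene with planted triplet patterns
#'
#' Places `spec$n_triplets` triangles of the requested geometry uniformly in
#' the ROI (eroded by the triangle circumradius so planted patterns never
#' straddle the boundary) with uniformly random orientation, dresses each
#' vertex with molecules, and adds CSR background per channel.
#'
#' @param spec a [scene_spec()].
#' @return A list with `fields` (list of three [localization_field()]s) and
#'   `sites` (ground-truth data frame: triplet id, channel, site x/y, and the
#'   number of detected molecules per site).
#' @export
generate_triplet_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    L <- spec$roi_size
    verts <- triangle_vertices(spec$triplet_geometry)
    rad <- max(sqrt(rowSums(scale(verts, center = colMeans(verts),
                                  scale = FALSE)^2)))
    margin <- rad + 4 * spec$site_sigma + 4 * spec$localization_sigma
    if (2 * margin >= L) stop("ROI too small for the requested geometry")
    n <- spec$n_triplets
    cx <- stats::runif(n, margin, L - margin)
    cy <- stats::runif(n, margin, L - margin)
    phi <- stats::runif(n, -pi, pi)
    centroid <- colMeans(verts)

    sites <- vector("list", n)
    for (i in seq_len(n)) {
      R <- matrix(c(cos(phi[i]), -sin(phi[i]), sin(phi[i]), cos(phi[i])), 2L)
      v <- sweep(verts, 2L, centroid) %*% t(R)
      sites[[i]] <- data.frame(
        triplet = i, channel = 1:3,
        site_x = cx[i] + v[, 1], site_y = cy[i] + v[, 2]
      )
    }
    sites <- do.call(rbind, sites)

    fields <- vector("list", 3L)
    sites$n_detected <- 0L
    for (ch in 1:3) {
      idx <- which(sites$channel == ch)
      xs <- ys <- numeric(0)
      for (k in idx) {
        m <- stats::rpois(1L, spec$molecules_per_site[ch])
        det <- stats::rbinom(1L, m, spec$detection_efficiency[ch])
        sites$n_detected[k] <- det
        if (det > 0) {
          xs <- c(xs, sites$site_x[k] +
                    stats::rnorm(det, 0, spec$site_sigma) +
                    stats::rnorm(det, 0, spec$localization_sigma))
          ys <- c(ys, sites$site_y[k] +
                    stats::rnorm(det, 0, spec$site_sigma) +
                    stats::rnorm(det, 0, spec$localization_sigma))
        }
      }
      nbg <- stats::rpois(1L, spec$background_density[ch] * (L / 1000)^2)
      xs <- c(xs, stats::runif(nbg, 0, L))
      ys <- c(ys, stats::runif(nbg, 0, L))
      keep <- xs >= 0 & xs <= L & ys >= 0 & ys <= L
      fields[[ch]] <- localization_field(xs[keep], ys[keep],
                                         roi = c(0, L, 0, L), channel = ch)
    }
    list(fields = fields, sites = sites)
  })
}
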