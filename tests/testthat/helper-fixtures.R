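# Shared fixture builders; everything is generated in code, seeded.

# Skew-normal sampler (location/scale/shape parameterization) used as the
# independent oracle for the precision-distribution fit.
rsn_oracle <- function(n, xi, omega, alpha) {
  d <- alpha / sqrt(1 + alpha^2)
  u <- abs(stats::rnorm(n))
  v <- stats::rnorm(n)
  xi + omega * (d * u + sqrt(1 - d^2) * v)
}

# A cluster_set of n tight 5-point clusters placed uniformly in a 6x6 um ROI.
make_cluster_set <- function(n, seed, roi = c(0, 6000, 0, 6000),
                             pts_per = 5, spread = 8) {
  set.seed(seed)
  cx <- stats::runif(n, roi[1] + 100, roi[2] - 100)
  cy <- stats::runif(n, roi[3] + 100, roi[4] - 100)
  xs <- rep(cx, each = pts_per) + stats::rnorm(pts_per * n, 0, spread)
  ys <- rep(cy, each = pts_per) + stats::rnorm(pts_per * n, 0, spread)
  dbscan_clusters(localization_field(
    pmin(pmax(xs, roi[1]), roi[2]), pmin(pmax(ys, roi[3]), roi[4]), roi))
}

# Independent expected-photoelectron image: midpoint-rule integration of the
# 2D Gaussian PSF over each pixel on a fine subgrid (no pnorm/erf shared with
# the implementation).
expected_psf_image <- function(x0, y0, photons, sigma, nr, nc, sub = 41) {
  img <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    gx <- (j - 1) + (seq_len(sub) - 0.5) / sub
    gy <- (i - 1) + (seq_len(sub) - 0.5) / sub
    gauss <- outer(exp(-(gy - y0)^2 / (2 * sigma^2)),
                   exp(-(gx - x0)^2 / (2 * sigma^2))) / (2 * pi * sigma^2)
    img[i, j] <- photons * sum(gauss) / sub^2
  }
  img
}

# Brute-force O(N^2) radial pair histogram (oracle for g(r)/c(r)).
brute_pair_g <- function(field, bin_width, r_max, fieldB = NULL) {
  roi <- attr(field, "roi")
  edges <- seq(0, r_max, by = bin_width)
  refs <- which(field$x_nm >= roi[1] + r_max & field$x_nm <= roi[2] - r_max &
                  field$y_nm >= roi[3] + r_max & field$y_nm <= roi[4] - r_max)
  tgt <- if (is.null(fieldB)) field else fieldB
  counts <- numeric(length(edges) - 1)
  for (i in refs) {
    d <- sqrt((tgt$x_nm - field$x_nm[i])^2 + (tgt$y_nm - field$y_nm[i])^2)
    if (is.null(fieldB)) d <- d[-i]
    d <- d[d <= r_max]
    counts <- counts + tabulate(findInterval(d, edges), length(edges) - 1)
  }
  rho <- nrow(tgt) / ((roi[2] - roi[1]) * (roi[4] - roi[3]))
  list(g = counts / (length(refs) * pi * diff(edges^2) * rho),
       counts = counts, n_ref = length(refs))
}
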