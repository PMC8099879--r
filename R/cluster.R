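#' DBSCAN focus segmentation of a localization field
#'
#' Standard density-based spatial clustering: core points have at least
#' `min_pts` neighbours (the point itself included) within `eps`; clusters
#' are the connected components of core points plus their border points;
#' everything else is noise. Defaults follow the SMLM focus convention of
#' eps = 15 nm and min_pts = 3. Exact O(N^2) implementation.
#'
#' @param field a [localization_field()] (or data frame with `x_nm`/`y_nm`).
#' @param eps neighbourhood radius (nm, > 0), default 15.
#' @param min_pts minimum points per focus (>= 1), default 3.
#' @return A `cluster_set`: integer `labels` (0 = noise), list `clusters` of
#'   member index vectors, `centroids`, list `boundaries` of convex-hull
#'   boundary coordinates per cluster, and the source coordinates.
#' @export
dbscan_clusters <- function(field, eps = 15, min_pts = 3) {
  stop_if_not_number(eps, "eps", positive = TRUE)
  stopifnot(min_pts >= 1)
  n <- nrow(field)
  x <- field$x_nm; y <- field$y_nm
  labels <- integer(n)
  if (n > 0) {
    D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
    nbrs <- D2 <= eps^2
    core <- rowSums(nbrs) >= min_pts
    cl <- 0L
    for (i in seq_len(n)) {
      if (labels[i] != 0L || !core[i]) next
      cl <- cl + 1L
      labels[i] <- cl
      seeds <- which(nbrs[i, ] & labels == 0L)
      labels[seeds] <- cl
      while (length(seeds)) {
        j <- seeds[[1]]; seeds <- seeds[-1]
        if (core[j]) {
          new <- which(nbrs[j, ] & labels == 0L)
          labels[new] <- cl
          seeds <- c(seeds, new)
        }
      }
    }
  }
  ids <- sort(unique(labels[labels > 0L]))
  clusters <- lapply(ids, function(k) which(labels == k))
  centroids <- t(vapply(clusters, function(m) c(mean(x[m]), mean(y[m])),
                        numeric(2)))
  boundaries <- lapply(clusters, function(m) {
    if (length(m) <= 2L) return(cbind(x = x[m], y = y[m]))
    h <- grDevices::chull(x[m], y[m])
    cbind(x = x[m][h], y = y[m][h])
  })
  structure(list(labels = labels, clusters = clusters, centroids = centroids,
                 boundaries = boundaries, x = x, y = y,
                 noise = which(labels == 0L),
                 eps = eps, min_pts = min_pts, roi = attr(field, "roi")),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters, %d noise points (eps %g nm, min_pts %d)\n",
              length(x$clusters), length(x$noise), x$eps, x$min_pts))
  invisible(x)
}

# Edge-to-edge distance between the convex boundaries of two clusters:
# minimum over boundary-point pairs, 0 when the hulls overlap.
edge_to_edge_nnd <- function(ba, bb) {
  d <- sqrt(min(outer(ba[, 1], bb[, 1], "-")^2 +
                  outer(ba[, 2], bb[, 2], "-")^2))
  if (polygons_overlap(ba, bb)) 0 else d
}

# Overlap test for two convex point sets: any vertex of one inside the
# hull of the other (sufficient here; boundary-point distance covers the
# crossing-edge case within localization scale).
polygons_overlap <- function(a, b) {
  any_inside(a, b) || any_inside(b, a)
}

any_inside <- function(pts, poly) {
  if (nrow(poly) < 3L) return(FALSE)
  for (r in seq_len(nrow(pts))) {
    px <- pts[r, 1]; py <- pts[r, 2]
    sgn <- 0; inside <- TRUE
    np <- nrow(poly)
    for (e in seq_len(np)) {
      x1 <- poly[e, 1]; y1 <- poly[e, 2]
      x2 <- poly[e %% np + 1L, 1]; y2 <- poly[e %% np + 1L, 2]
      cr <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
      if (abs(cr) < 1e-12) next
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) { inside <- FALSE; break }
    }
    if (inside) return(TRUE)
  }
  FALSE
}

#' Colocalized cluster fraction by edge-to-edge NND
#'
#' Two clusters are colocalized when the edge-to-edge nearest-neighbour
#' distance between their convex boundaries is at most `threshold`
#' (default 5 nm). The fraction is the number of colocalized pairs divided
#' by the cluster count of the queried species, reported in both directions.
#'
#' @param setA,setB `cluster_set`s from one registered ROI.
#' @param threshold colocalization NND threshold (nm), default 5.
#' @return A `coloc_result`: `fraction_a` (A clusters with a colocalized B
#'   partner), `fraction_b`, `pairs` (count of colocalized A-B pairs),
#'   `nnd_a` (per-A-cluster NND to the nearest B cluster), flags.
#' @export
coloc_fraction <- function(setA, setB, threshold = 5) {
  stop_if_not_number(threshold, "threshold", nonneg = TRUE)
  na <- length(setA$clusters); nb <- length(setB$clusters)
  if (na == 0 || nb == 0) {
    return(structure(list(fraction_a = 0, fraction_b = 0, pairs = 0L,
                          nnd_a = numeric(0), threshold = threshold,
                          flags = "empty_cluster_set"),
                     class = "coloc_result"))
  }
  # branch-and-bound on centroid distances: the edge-to-edge distance of a
  # pair is bounded below by centroid distance minus both hull radii, so
  # exact hull computations are needed only while the bound can still beat
  # the current best or the threshold
  stats_of <- function(b) {
    cx <- mean(b[, 1]); cy <- mean(b[, 2])
    c(cx, cy, sqrt(max((b[, 1] - cx)^2 + (b[, 2] - cy)^2)))
  }
  sa <- t(vapply(setA$boundaries, stats_of, numeric(3)))
  sb <- t(vapply(setB$boundaries, stats_of, numeric(3)))
  cd <- sqrt(outer(sa[, 1], sb[, 1], "-")^2 + outer(sa[, 2], sb[, 2], "-")^2)
  lower <- pmax(cd - outer(sa[, 3], sb[, 3], "+"), 0)
  nnd <- matrix(Inf, na, nb)
  hit <- matrix(FALSE, na, nb)
  for (i in seq_len(na)) {
    best <- Inf
    for (j in order(lower[i, ])) {
      if (lower[i, j] > max(best, threshold)) break
      nnd[i, j] <- edge_to_edge_nnd(setA$boundaries[[i]], setB$boundaries[[j]])
      if (nnd[i, j] < best) best <- nnd[i, j]
      if (nnd[i, j] <= threshold) hit[i, j] <- TRUE
    }
    nnd[i, is.infinite(nnd[i, ])] <- pmax(lower[i, is.infinite(nnd[i, ])],
                                          best)
  }
  structure(list(
    fraction_a = mean(apply(hit, 1L, any)),
    fraction_b = mean(apply(hit, 2L, any)),
    pairs = sum(hit),
    nnd_a = apply(nnd, 1L, min),
    threshold = threshold, flags = character(0)
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> fraction A->B %.3f, B->A %.3f, %d pairs (NND <= %g nm)\n",
              x$fraction_a, x$fraction_b, x$pairs, x$threshold))
  invisible(x)
}

#' Randomized colocalization baseline
#'
#' Monte-Carlo null for [coloc_fraction()]: every cluster of `setB` is
#' rigidly translated to a uniform position and rotated by a uniform angle
#' (rejection-sampled to stay wholly inside the ROI) and the colocalized
#' fraction is recomputed; the observed fraction is summarized as a z-score
#' against the resulting baseline.
#'
#' @param setA,setB `cluster_set`s sharing a registered ROI.
#' @param roi length-4 ROI (nm); defaults to the ROI stored on `setB`.
#' @param threshold NND threshold (nm), default 5.
#' @param n_iter number of randomizations (>= 10), default 100.
#' @param seed integer seed.
#' @return List: `observed`, `baseline_mean`, `baseline_sd`, `z`,
#'   `baseline` (per-iteration fractions).
#' @export
randomized_baseline <- function(setA, setB, roi = NULL, threshold = 5,
                                n_iter = 100, seed = NULL) {
  if (n_iter < 10) stop("n_iter must be >= 10")
  roi <- roi %||% setB$roi
  if (is.null(roi)) stop("no ROI available; pass `roi`")
  obs <- coloc_fraction(setA, setB, threshold)$fraction_a
  with_seed(seed, {
    base <- vapply(seq_len(n_iter), function(it) {
      rb <- setB
      rb$boundaries <- lapply(setB$boundaries, function(b)
        random_rigid_place(b, roi))
      coloc_fraction(setA, rb, threshold)$fraction_a
    }, numeric(1))
    m <- mean(base); s <- stats::sd(base)
    z <- if (s > 0) (obs - m) / s else if (obs == m) 0 else NA_real_
    list(observed = obs, baseline_mean = m, baseline_sd = s, z = z,
         baseline = base)
  })
}

# Uniformly translate + rotate a boundary-point set inside the ROI
# (rejection sampling on the rotated bounding box).
random_rigid_place <- function(b, roi) {
  cx <- mean(b[, 1]); cy <- mean(b[, 2])
  rel <- cbind(b[, 1] - cx, b[, 2] - cy)
  for (try in 1:1000) {
    phi <- stats::runif(1, -pi, pi)
    R <- matrix(c(cos(phi), -sin(phi), sin(phi), cos(phi)), 2L)
    rot <- rel %*% t(R)
    xr <- range(rot[, 1]); yr <- range(rot[, 2])
    if (roi[1] - xr[1] > roi[2] - xr[2] || roi[3] - yr[1] > roi[4] - yr[2])
      stop("cluster larger than the ROI")
    nx <- stats::runif(1, roi[1] - xr[1], roi[2] - xr[2])
    ny <- stats::runif(1, roi[3] - yr[1], roi[4] - yr[2])
    out <- cbind(x = rot[, 1] + nx, y = rot[, 2] + ny)
    if (all(out[, 1] >= roi[1] & out[, 1] <= roi[2] &
              out[, 2] >= roi[3] & out[, 2] <= roi[4]))
      return(out)
  }
  stop("failed to place cluster inside the ROI")
}
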