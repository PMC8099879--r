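#' Triple-correlation (TC) analysis of three-channel point patterns
#'
#' @description
#' The TC function quantifies recurrent three-species triplet geometries in
#' a multi-colour SMLM scene. For displacements `r1 = (r1, theta)` and
#' `r2 = (r2, theta + dtheta)` it averages the product of the local density
#' fluctuations of channels 2 and 3 at the two displaced positions over every
#' coordinate of channel 1 and over `theta` in `[-pi, pi]`, normalized by the
#' product of the channel densities. Because triplets are randomly oriented,
#' the angular average collapses `f(r1, r2, dtheta)` onto a symmetric
#' `f(r1, r2, r3)` grid, `r3` being the distance between the two displaced
#' vertices. A positive excess at a cell means the three species recur at
#' that triangle geometry more often than chance.
#'
#' Density fluctuations at a displacement are estimated by sector-annulus
#' bin counting with exact bin-area normalization (bin area
#' `(r_out^2 - r_in^2)/2 * dtheta_sector`, `dtheta_sector = 2 pi / n_theta`).
#' Channel-1 reference points are restricted to the ROI eroded by `r_max`.
#'
#' @name triple-correlation
NULL

#' Third-side transform of the TC angular average
#'
#' Collapses a polar cell (`r1`, `r2`, angle offset `dtheta`) onto the third
#' side length via `r3^2 = r1^2 + r2^2 + 2 r1 r2 cos(dtheta)`, with `dtheta`
#' measured as the supplement of the angle between the two displacement
#' vectors (so `dtheta = 0` means anti-parallel displacements, giving
#' `r3 = r1 + r2`).
#'
#' @param r1,r2 displacement radii (nm).
#' @param dtheta angle (radians).
#' @return `r3` (nm).
#' @export
tc_r3 <- function(r1, r2, dtheta) {
  sqrt(pmax(r1^2 + r2^2 + 2 * r1 * r2 * cos(dtheta), 0))
}

# delta-rho array [n_ref, n_r, n_theta] of `field` around reference points.
tc_delta_array <- function(refxy, field, r_edges, n_theta, rho_nm) {
  n_ref <- nrow(refxy)
  n_r <- length(r_edges) - 1L
  r_max <- r_edges[length(r_edges)]
  dtheta <- 2 * pi / n_theta
  px <- field$x_nm; py <- field$y_nm
  idx_all <- vector("list", n_ref)
  for (i in seq_len(n_ref)) {
    dx <- px - refxy[i, 1]; dy <- py - refxy[i, 2]
    d2 <- dx * dx + dy * dy
    keep <- d2 <= r_max^2 & d2 > 0
    if (!any(keep)) next
    d <- sqrt(d2[keep])
    rb <- findInterval(d, r_edges)
    rb[rb > n_r] <- n_r
    tb <- floor((atan2(dy[keep], dx[keep]) + pi) / dtheta) + 1L
    tb[tb > n_theta] <- 1L   # atan2 == pi wraps to the first sector
    idx_all[[i]] <- i + n_ref * (rb - 1L) + n_ref * n_r * (tb - 1L)
  }
  counts <- tabulate(unlist(idx_all), nbins = n_ref * n_r * n_theta)
  areas <- diff(r_edges^2) / 2 * dtheta   # per r bin
  arr <- array(counts, dim = c(n_ref, n_r, n_theta))
  list(delta = sweep(arr, 2L, areas, "/") - rho_nm,
       pos = array(as.numeric(counts > 0), dim = dim(arr)))
}

# Raw TC grid f[r1, r2, shift] from the two delta arrays, plus the per-cell
# support: the number of (visit, theta) samples where both displaced bins
# actually contain points (observed triple coincidences).
tc_raw_f <- function(DA2, DA3, rho2_nm, rho3_nm) {
  D2 <- DA2$delta; D3 <- DA3$delta
  n_ref <- dim(D2)[1]; n_r <- dim(D2)[2]; n_theta <- dim(D2)[3]
  A <- matrix(aperm(D2, c(2L, 1L, 3L)), n_r)          # [n_r, n_ref*n_theta]
  Ai <- matrix(aperm(DA2$pos, c(2L, 1L, 3L)), n_r)
  f <- array(NA_real_, dim = c(n_r, n_r, n_theta))
  supp <- array(0, dim = c(n_r, n_r, n_theta))
  norm <- n_ref * n_theta * rho2_nm * rho3_nm
  for (s in 0:(n_theta - 1L)) {
    perm <- ((seq_len(n_theta) - 1L + s) %% n_theta) + 1L
    B <- matrix(aperm(D3[, , perm, drop = FALSE], c(2L, 1L, 3L)), n_r)
    Bi <- matrix(aperm(DA3$pos[, , perm, drop = FALSE], c(2L, 1L, 3L)), n_r)
    f[, , s + 1L] <- (A %*% t(B)) / norm
    supp[, , s + 1L] <- Ai %*% t(Bi)
  }
  list(f = f, support = supp)
}

# Collapse f[r1, r2, shift] onto the (r1, r2, r3) grid (mean over the shifts
# mapping into each r3 bin). Angle offsets between sector centres are
# s * 2pi/n_theta; the third side uses the supplement convention of tc_r3().
tc_collapse <- function(f_raw, supp_raw, r_centers, bin_width) {
  n_r <- length(r_centers); n_theta <- dim(f_raw)[3]
  n_r3 <- ceiling(2 * max(r_centers) / bin_width) + 1L
  f3 <- array(0, dim = c(n_r, n_r, n_r3))
  sp3 <- array(0, dim = c(n_r, n_r, n_r3))
  nsh <- array(0L, dim = c(n_r, n_r, n_r3))
  ang <- (seq_len(n_theta) - 1L) * 2 * pi / n_theta
  for (s in seq_len(n_theta)) {
    r3 <- tc_r3(outer(r_centers, rep(1, n_r)),
                outer(rep(1, n_r), r_centers), pi - ang[s])
    kb <- pmin(pmax(floor(r3 / bin_width) + 1L, 1L), n_r3)
    for (i in seq_len(n_r)) for (j in seq_len(n_r)) {
      k <- kb[i, j]
      f3[i, j, k] <- f3[i, j, k] + f_raw[i, j, s]
      sp3[i, j, k] <- sp3[i, j, k] + supp_raw[i, j, s]
      nsh[i, j, k] <- nsh[i, j, k] + 1L
    }
  }
  f3 <- ifelse(nsh > 0, f3 / pmax(nsh, 1L), NA_real_)
  list(f = f3, support = sp3, n_shift = nsh,
       r3_centers = (seq_len(n_r3) - 0.5) * bin_width)
}

tc_check_fields <- function(field1, field2, field3, r_max) {
  roi <- roi_of(field1)
  for (f in list(field2, field3))
    if (any(abs(roi_of(f) - roi) > 1e-6)) stop("fields must share one ROI")
  if (r_max >= min(roi[2] - roi[1], roi[4] - roi[3]) / 2)
    stop("r_max must be below half the ROI side")
  for (f in list(field1, field2, field3))
    if (nrow(f) < 10) stop("each channel needs >= 10 points")
  roi
}

#' Compute the TC map of three registered fields
#'
#' @param field1,field2,field3 registered [localization_field()]s sharing
#'   one ROI, each with at least 10 points. Channel 1 supplies the visited
#'   reference coordinates.
#' @param r_max maximum displacement radius (nm), default 300.
#' @param bin_width radial bin width (nm), default 20.
#' @param n_theta number of angular sectors, default 18.
#' @return A `tc_map`: raw grid `f_raw[r1, r2, shift]`, collapsed grid
#'   `f[r1, r2, r3]` with per-cell shift multiplicities, bin geometry,
#'   channel densities (points/um^2) and the reference count.
#' @export
compute_tc_map <- function(field1, field2, field3, r_max = 300,
                           bin_width = 20, n_theta = 18) {
  roi <- tc_check_fields(field1, field2, field3, r_max)
  r_edges <- seq(0, r_max, by = bin_width)
  ref_idx <- erode_indices(field1, r_max)
  if (length(ref_idx) < 1) stop("no channel-1 reference points after erosion")
  refxy <- cbind(field1$x_nm, field1$y_nm)[ref_idx, , drop = FALSE]
  area_nm2 <- (roi[2] - roi[1]) * (roi[4] - roi[3])
  rho_nm <- c(nrow(field1), nrow(field2), nrow(field3)) / area_nm2
  D2 <- tc_delta_array(refxy, field2, r_edges, n_theta, rho_nm[2])
  D3 <- tc_delta_array(refxy, field3, r_edges, n_theta, rho_nm[3])
  raw <- tc_raw_f(D2, D3, rho_nm[2], rho_nm[3])
  r_centers <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  col <- tc_collapse(raw$f, raw$support, r_centers, bin_width)
  structure(list(
    f_raw = raw$f, f = col$f, support = col$support, n_shift = col$n_shift,
    r_centers = r_centers, r3_centers = col$r3_centers,
    bin_width = bin_width, r_max = r_max, n_theta = n_theta,
    rho_um2 = rho_nm * 1e6, n_ref = nrow(refxy), roi = roi
  ), class = "tc_map")
}

#' @export
print.tc_map <- function(x, ...) {
  cat(sprintf(
    "<tc_map> %d x %d x %d (r1, r2, r3) grid, bin %g nm, %d reference points\n",
    length(x$r_centers), length(x$r_centers), length(x$r3_centers),
    x$bin_width, x$n_ref))
  invisible(x)
}

#' Monte-Carlo null TC maps (channel 3 resampled as CSR)
#'
#' Recomputes the TC map `n_rand` times with channel 3 replaced by a CSR
#' field of matched density; channels 1-2 (and hence their delta array) are
#' preserved. The nulls calibrate per-cell z-scores and the family-wise
#' amplitude gate of [find_tc_triplets()].
#'
#' @inheritParams compute_tc_map
#' @param n_rand number of null maps (>= 2), default 20.
#' @param seed integer seed.
#' @return List of `tc_map` objects.
#' @export
tc_null_maps <- function(field1, field2, field3, r_max = 300, bin_width = 20,
                         n_theta = 18, n_rand = 20, seed = NULL) {
  if (n_rand < 2) stop("n_rand must be >= 2")
  roi <- tc_check_fields(field1, field2, field3, r_max)
  r_edges <- seq(0, r_max, by = bin_width)
  ref_idx <- erode_indices(field1, r_max)
  refxy <- cbind(field1$x_nm, field1$y_nm)[ref_idx, , drop = FALSE]
  area_nm2 <- (roi[2] - roi[1]) * (roi[4] - roi[3])
  rho_nm <- c(nrow(field1), nrow(field2), nrow(field3)) / area_nm2
  D2 <- tc_delta_array(refxy, field2, r_edges, n_theta, rho_nm[2])
  r_centers <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  with_seed(seed, {
    lapply(seq_len(n_rand), function(k) {
      n3 <- nrow(field3)
      null3 <- localization_field(
        stats::runif(n3, roi[1], roi[2]), stats::runif(n3, roi[3], roi[4]),
        roi = roi, channel = field3$channel[1] %||% 3L)
      D3 <- tc_delta_array(refxy, null3, r_edges, n_theta, rho_nm[3])
      raw <- tc_raw_f(D2, D3, rho_nm[2], rho_nm[3])
      col <- tc_collapse(raw$f, raw$support, r_centers, bin_width)
      structure(list(
        f_raw = raw$f, f = col$f, support = col$support,
        n_shift = col$n_shift,
        r_centers = r_centers, r3_centers = col$r3_centers,
        bin_width = bin_width, r_max = r_max, n_theta = n_theta,
        rho_um2 = rho_nm * 1e6, n_ref = nrow(refxy), roi = roi
      ), class = "tc_map")
    })
  })
}

# Per-cell null mean/sd arrays from a list of tc_maps.
tc_null_stats <- function(nulls) {
  stack <- vapply(nulls, function(m) m$f, nulls[[1]]$f)
  nd <- length(dim(nulls[[1]]$f))
  list(mean = apply(stack, seq_len(nd), mean),
       sd = apply(stack, seq_len(nd), stats::sd))
}

#' Per-cell z-scores of a TC map against its nulls
#'
#' @param map a `tc_map`.
#' @param nulls list of null `tc_map`s on the same grid.
#' @return Array of z-scores on the collapsed (r1, r2, r3) grid.
#' @export
tc_zscores <- function(map, nulls) {
  for (nl in nulls)
    if (!all(dim(nl$f) == dim(map$f))) stop("null grid does not match map")
  ns <- tc_null_stats(nulls)
  z <- (map$f - ns$mean) / ns$sd
  z[!is.finite(z)] <- NA_real_
  z
}

#' Detect significant TC triplets
#'
#' Candidates are local maxima (26-neighbourhood) of the collapsed TC
#' amplitude whose per-cell z-score against the nulls reaches `z_threshold`;
#' one triplet is reported per connected above-threshold region (the
#' maximum-z cell, ties broken towards smaller `r1 + r2 + r3`). A
#' family-wise amplitude gate is applied on top: a candidate's amplitude
#' must also exceed the null maps' scene-wide maximum amplitude at the tail
#' probability matching `z_threshold` (a Gumbel quantile fitted by moments
#' to the null maxima — the extreme-value calibration of a whole-grid
#' search; per-cell z alone would be multiplied over ~10^3 cells).
#'
#' @param map a `tc_map` from [compute_tc_map()].
#' @param nulls list of `tc_map`s from [tc_null_maps()] on the same grid.
#' @param z_threshold significance threshold (default 3).
#' @param min_support minimum number of observed triple coincidences backing
#'   a cell (default 3, echoing the DBSCAN minimum-point convention): a
#'   recurrent pattern must be seen repeatedly, which shields sparse scenes
#'   from single-coincidence amplitude spikes.
#' @return A data frame of class `tc_triplets` (possibly 0 rows), ordered by
#'   decreasing z: `r1_nm`, `r2_nm`, `r3_nm`, `f`, `z`, `support`.
#' @export
find_tc_triplets <- function(map, nulls, z_threshold = 3, min_support = 3) {
  z <- tc_zscores(map, nulls)
  f <- map$f
  valid <- is.finite(f) & map$n_shift > 0 & map$support >= min_support
  null_max <- vapply(nulls, function(m) max(m$f[is.finite(m$f)]), 0)
  # Gumbel moment fit of the null scene maxima; gate at the quantile whose
  # exceedance probability matches the z_threshold normal tail
  beta <- stats::sd(null_max) * sqrt(6) / pi
  mu_g <- mean(null_max) - 0.57721566 * beta
  alpha <- stats::pnorm(-z_threshold)
  gate <- mu_g - beta * log(-log(1 - alpha))

  dims <- dim(f)
  above <- which(valid & !is.na(z) & z >= z_threshold, arr.ind = TRUE)
  empty <- data.frame(r1_nm = numeric(0), r2_nm = numeric(0),
                      r3_nm = numeric(0), f = numeric(0), z = numeric(0),
                      support = numeric(0))
  class(empty) <- c("tc_triplets", "data.frame")
  if (nrow(above) == 0) return(empty)

  # connected components (26-connectivity) of the above-threshold mask
  key <- function(ijk) (ijk[, 1] - 1) + dims[1] * ((ijk[, 2] - 1) +
                                                     dims[2] * (ijk[, 3] - 1))
  in_mask <- new.env(hash = TRUE)
  for (r in seq_len(nrow(above)))
    assign(as.character(key(above[r, , drop = FALSE])), r, envir = in_mask)
  comp <- integer(nrow(above)); nc <- 0L
  for (r in seq_len(nrow(above))) {
    if (comp[r]) next
    nc <- nc + 1L
    queue <- r
    comp[r] <- nc
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      ijk <- above[cur, ]
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (!di && !dj && !dk) next
        nb <- ijk + c(di, dj, dk)
        if (any(nb < 1) || any(nb > dims)) next
        id <- as.character((nb[1] - 1) + dims[1] * ((nb[2] - 1) +
                                                      dims[2] * (nb[3] - 1)))
        hit <- mget(id, envir = in_mask, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && !comp[hit]) {
          comp[hit] <- nc
          queue <- c(queue, hit)
        }
      }
    }
  }

  is_local_max <- function(ijk) {
    v <- f[ijk[1], ijk[2], ijk[3]]
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (!di && !dj && !dk) next
      nb <- ijk + c(di, dj, dk)
      if (any(nb < 1) || any(nb > dims)) next
      w <- f[nb[1], nb[2], nb[3]]
      if (is.finite(w) && w > v) return(FALSE)
    }
    TRUE
  }

  rows <- lapply(seq_len(nc), function(cc) {
    members <- which(comp == cc)
    zz <- z[above[members, , drop = FALSE]]
    rsum <- map$r_centers[above[members, 1]] + map$r_centers[above[members, 2]] +
      map$r3_centers[above[members, 3]]
    lm <- vapply(members, function(r) is_local_max(above[r, ]), TRUE)
    # mode cell of the region: the amplitude peak among its local maxima
    # (tie-break larger z, then smaller r1+r2+r3); a region with no interior
    # local maximum falls back to its largest-amplitude cell
    pool <- if (any(lm)) which(lm) else seq_along(members)
    ff <- f[above[members, , drop = FALSE]]
    best <- pool[order(-ff[pool], -zz[pool], rsum[pool])][1]
    ijk <- above[members[best], ]
    fv <- f[ijk[1], ijk[2], ijk[3]]
    if (fv < gate) return(NULL)
    data.frame(r1_nm = map$r_centers[ijk[1]], r2_nm = map$r_centers[ijk[2]],
               r3_nm = map$r3_centers[ijk[3]], f = fv,
               z = z[ijk[1], ijk[2], ijk[3]],
               support = map$support[ijk[1], ijk[2], ijk[3]])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tc_triplets", "data.frame")
  out
}

#' Conditional local density C3 at a triplet vertex
#'
#' Ratio of the triple-product density term to the channel-1/channel-2 pair
#' term, `C3 = <d_rho1 d_rho2 d_rho3> / <d_rho1 d_rho2>`, evaluated at the
#' triplet's grid cells: the local density of the third species at its
#' vertex given a correlated 1-2 pair. An independent third channel gives
#' C3 near 0, and uniform channel-3 background cancels by construction.
#'
#' @param field1,field2,field3 registered fields (channel roles as in
#'   [compute_tc_map()]).
#' @param triplet one row of a `tc_triplets` data frame (or a list with
#'   `r1_nm`, `r2_nm`, `r3_nm`).
#' @inheritParams compute_tc_map
#' @return Conditional density in points per square micrometre.
#' @export
conditional_density <- function(field1, field2, field3, triplet,
                                r_max = 300, bin_width = 20, n_theta = 18) {
  roi <- tc_check_fields(field1, field2, field3, r_max)
  g <- c(triplet$r1_nm[1], triplet$r2_nm[1], triplet$r3_nm[1])
  if (any(!is.finite(g)) ||
      g[1] + g[2] < g[3] || g[1] + g[3] < g[2] || g[2] + g[3] < g[1])
    stop("triplet geometry must satisfy the triangle inequality")
  r_edges <- seq(0, r_max, by = bin_width)
  ref_idx <- erode_indices(field1, r_max)
  refxy <- cbind(field1$x_nm, field1$y_nm)[ref_idx, , drop = FALSE]
  area_nm2 <- (roi[2] - roi[1]) * (roi[4] - roi[3])
  rho_nm <- c(nrow(field1), nrow(field2), nrow(field3)) / area_nm2
  D2 <- tc_delta_array(refxy, field2, r_edges, n_theta, rho_nm[2])$delta
  D3 <- tc_delta_array(refxy, field3, r_edges, n_theta, rho_nm[3])$delta
  r_centers <- (r_edges[-1] + r_edges[-length(r_edges)]) / 2
  i1 <- which.min(abs(r_centers - g[1]))
  i2 <- which.min(abs(r_centers - g[2]))
  k3 <- floor(g[3] / bin_width) + 1L
  ang <- (seq_len(n_theta) - 1L) * 2 * pi / n_theta
  r3s <- tc_r3(r_centers[i1], r_centers[i2], pi - ang)
  shifts <- which(pmin(pmax(floor(r3s / bin_width) + 1L, 1L),
                       ceiling(2 * max(r_centers) / bin_width) + 1L) == k3)
  if (!length(shifts)) stop("no angular cells map onto the triplet geometry")
  n_ref <- nrow(refxy)
  num <- 0
  for (s in shifts) {
    perm <- ((seq_len(n_theta) - 1L + (s - 1L)) %% n_theta) + 1L
    num <- num + sum(D2[, i1, ] * D3[, i2, perm]) / (n_ref * n_theta)
  }
  num <- num / length(shifts)             # <d_rho1 d_rho2 d_rho3> / <rho1>
  den <- mean(D2[, i1, ])                 # <d_rho1 d_rho2> / <rho1>
  if (den <= 0)
    stop("no significant pair support: 1-2 pair correlation term is <= 0 at r1")
  (num / den) * 1e6
}

#' Brute-force triplet counting (testing oracle)
#'
#' Exhaustively counts point triplets (one point per channel) whose three
#' pairwise distances match `geometry = c(r12, r13, r23)` within
#' `tolerance`. Cubic cost; intended as the independent oracle for TC
#' detection on desk-scale scenes.
#'
#' @param field1,field2,field3 fields (any point sets with `x_nm`, `y_nm`).
#' @param geometry length-3 distances (nm): 1-2, 1-3, 2-3.
#' @param tolerance absolute distance tolerance (nm, > 0).
#' @return Integer count.
#' @export
brute_force_triplets <- function(field1, field2, field3, geometry, tolerance) {
  stop_if_not_number(tolerance, "tolerance", positive = TRUE)
  if (nrow(field1) == 0 || nrow(field2) == 0 || nrow(field3) == 0) return(0L)
  d12 <- sqrt(outer(field1$x_nm, field2$x_nm, "-")^2 +
                outer(field1$y_nm, field2$y_nm, "-")^2)
  d13 <- sqrt(outer(field1$x_nm, field3$x_nm, "-")^2 +
                outer(field1$y_nm, field3$y_nm, "-")^2)
  d23 <- sqrt(outer(field2$x_nm, field3$x_nm, "-")^2 +
                outer(field2$y_nm, field3$y_nm, "-")^2)
  P12 <- abs(d12 - geometry[1]) <= tolerance
  A <- abs(d13 - geometry[2]) <= tolerance
  B <- abs(d23 - geometry[3]) <= tolerance
  as.integer(round(sum((A %*% t(B)) * P12)))
}

#' Frequency of a recurrent triplet pattern per reference pattern
#'
#' Normalizes the brute-force instance count at each significant triplet
#' geometry (tolerance = one grid bin) by a co-analyzed reference-pattern
#' count (e.g. the all-replisome triplet count of the same nucleus).
#'
#' @param triplets a `tc_triplets` data frame from [find_tc_triplets()].
#' @param field1,field2,field3 the fields the triplets were detected in.
#' @param reference_pattern_count reference count (> 0).
#' @param tolerance matching tolerance (nm); defaults to one 20-nm grid bin.
#' @return List with `frequency`, `instances`, `reference_pattern_count`.
#' @export
triplet_frequency <- function(triplets, field1, field2, field3,
                              reference_pattern_count, tolerance = 20) {
  if (!is.numeric(reference_pattern_count) || reference_pattern_count <= 0)
    stop("reference_pattern_count must be > 0")
  inst <- 0L
  for (r in seq_len(nrow(triplets))) {
    inst <- inst + brute_force_triplets(
      field1, field2, field3,
      c(triplets$r1_nm[r], triplets$r2_nm[r], triplets$r3_nm[r]), tolerance)
  }
  list(frequency = inst / reference_pattern_count, instances = inst,
       reference_pattern_count = reference_pattern_count)
}
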