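#' Bead-calibrated polynomial channel registration
#'
#' Multi-colour SMLM channels are mapped onto a reference channel with a
#' second-degree polynomial warp fitted to fiducial bead localizations,
#' correcting chromatic aberration. Beads are paired by mutual nearest
#' neighbour within a capture radius; the warp is solved by least squares on
#' centred/scaled coordinates and reported as coefficients over the
#' monomials `{1, x, y, x^2, xy, y^2}` in nm units.
#'
#' @param reference_beads,target_beads [localization_field()]s (or data
#'   frames with `x_nm`, `y_nm`) of the same bead slide imaged in the
#'   reference and target channels.
#' @param capture_radius pairing radius (nm), default 500.
#' @param degree polynomial degree, 1 (affine) or 2 (default).
#' @return A `channel_mapping` object: lists `coef_x`, `coef_y` (length 6
#'   coefficients over `{1, x, y, x^2, xy, y^2}`, zero-padded for degree 1),
#'   `rms_residual_nm`, `n_beads`, `degree`.
#' @export
fit_channel_map <- function(reference_beads, target_beads,
                            capture_radius = 500, degree = 2) {
  stopifnot(degree %in% 1:2)
  pr <- pair_mutual_nn(reference_beads, target_beads, capture_radius)
  need <- if (degree == 2) 6L else 3L
  if (nrow(pr) < need)
    stop(sprintf("only %d bead pairs; need >= %d for degree %d",
                 nrow(pr), need, degree))
  tx <- target_beads$x_nm[pr$target]; ty <- target_beads$y_nm[pr$target]
  rx <- reference_beads$x_nm[pr$ref]; ry <- reference_beads$y_nm[pr$ref]
  cx <- mean(tx); cy <- mean(ty)
  sx <- max(stats::sd(tx), 1e-9); sy <- max(stats::sd(ty), 1e-9)
  u <- (tx - cx) / sx; v <- (ty - cy) / sy
  M <- if (degree == 2) cbind(1, u, v, u^2, u * v, v^2) else cbind(1, u, v)
  qrM <- qr(M)
  if (qrM$rank < ncol(M))
    stop("degenerate bead layout: design matrix is rank deficient")
  bx <- qr.coef(qrM, rx); by <- qr.coef(qrM, ry)
  res <- sqrt(mean((M %*% bx - rx)^2 + (M %*% by - ry)^2))
  mapping <- structure(list(
    coef_x = expand_poly_coef(bx, cx, cy, sx, sy, degree),
    coef_y = expand_poly_coef(by, cx, cy, sx, sy, degree),
    center = c(cx, cy), scale = c(sx, sy),
    beta_x = bx, beta_y = by, degree = degree,
    rms_residual_nm = res, n_beads = nrow(pr)
  ), class = "channel_mapping")
  mapping
}

# Mutual nearest-neighbour bead pairing within a capture radius; ambiguous
# (non-mutual) beads are dropped.
pair_mutual_nn <- function(ref, tar, radius) {
  if (nrow(ref) == 0 || nrow(tar) == 0)
    return(data.frame(ref = integer(0), target = integer(0)))
  D <- outer(ref$x_nm, tar$x_nm, "-")^2 + outer(ref$y_nm, tar$y_nm, "-")^2
  nr <- apply(D, 1L, which.min)          # ref -> nearest target
  nt <- apply(D, 2L, which.min)          # target -> nearest ref
  ok <- which(nt[nr] == seq_len(nrow(ref)) &
                D[cbind(seq_len(nrow(ref)), nr)] <= radius^2)
  data.frame(ref = ok, target = nr[ok])
}

# Expand coefficients fitted on u = (x-cx)/sx, v = (y-cy)/sy back to raw-nm
# monomials {1, x, y, x^2, xy, y^2}.
expand_poly_coef <- function(b, cx, cy, sx, sy, degree) {
  if (degree == 1) b <- c(b, 0, 0, 0)
  # contributions of each scaled monomial to the raw monomials
  out <- numeric(6)
  # constant
  out[1] <- b[1] - b[2] * cx / sx - b[3] * cy / sy +
    b[4] * cx^2 / sx^2 + b[5] * cx * cy / (sx * sy) + b[6] * cy^2 / sy^2
  out[2] <- b[2] / sx - 2 * b[4] * cx / sx^2 - b[5] * cy / (sx * sy)
  out[3] <- b[3] / sy - 2 * b[6] * cy / sy^2 - b[5] * cx / (sx * sy)
  out[4] <- b[4] / sx^2
  out[5] <- b[5] / (sx * sy)
  out[6] <- b[6] / sy^2
  names(out) <- c("1", "x", "y", "x2", "xy", "y2")
  out
}

#' @export
print.channel_mapping <- function(x, ...) {
  cat(sprintf("<channel_mapping> degree %d, %d beads, RMS residual %.3g nm\n",
              x$degree, x$n_beads, x$rms_residual_nm))
  invisible(x)
}

#' Apply a fitted channel mapping to a localization field
#'
#' Transforms coordinates with the fitted polynomial warp; precision and all
#' other per-point fields are carried through unchanged. The ROI is widened
#' where needed so every mapped point stays inside it.
#'
#' @param mapping a `channel_mapping` from [fit_channel_map()].
#' @param table a [localization_field()] or data frame with `x_nm`, `y_nm`.
#' @return The table with transformed coordinates.
#' @export
apply_channel_map <- function(mapping, table) {
  if (!inherits(mapping, "channel_mapping"))
    stop("`mapping` must be a fitted channel_mapping")
  x <- table$x_nm; y <- table$y_nm
  M <- cbind(1, x, y, x^2, x * y, y^2)
  newx <- drop(M %*% mapping$coef_x)
  newy <- drop(M %*% mapping$coef_y)
  roi <- attr(table, "roi")
  if (!is.null(roi) && length(newx)) {
    attr(table, "roi") <- c(min(roi[1], newx), max(roi[2], newx),
                            min(roi[3], newy), max(roi[4], newy))
  }
  table$x_nm <- newx
  table$y_nm <- newy
  table
}
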