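#' Frame-wise FRET efficiency of a trajectory
#'
#' `E_t = acceptor / (acceptor + donor)`, clipped to `[0, 1]`. Frames whose
#' total intensity falls below 10% of the trajectory's median total are
#' masked as dark/bleached (`NA`); an all-zero frame is masked with a
#' warning.
#'
#' @param traj data frame with `donor` and `acceptor` columns.
#' @param dark_fraction masking threshold as a fraction of the median total
#'   intensity (default 0.1).
#' @return Numeric vector of efficiencies with `NA` at masked frames.
#' @export
fret_efficiency <- function(traj, dark_fraction = 0.1) {
  tot <- traj$donor + traj$acceptor
  if (any(tot == 0)) warning("all-zero frame(s) masked")
  e <- ifelse(tot > 0, traj$acceptor / tot, NA_real_)
  e <- pmin(pmax(e, 0), 1)
  med <- stats::median(tot[tot > 0])
  if (is.finite(med)) e[tot < dark_fraction * med] <- NA_real_
  e
}

pool_efficiencies <- function(trajs) {
  if (is.list(trajs) && !is.null(trajs$trajectories)) trajs <- trajs$trajectories
  if (is.data.frame(trajs)) trajs <- list(trajs)
  if (length(trajs) < 2) stop("need at least 2 trajectories to pool")
  lapply(trajs, fret_efficiency)
}

#' Two-Gaussian decomposition of the pooled FRET histogram
#'
#' Pools frame-wise efficiencies over trajectories, histograms them on
#' `n_bins` bins over `[0, 1]` and fits the counts with two independent
#' Gaussian curves. The unfolded fraction is the low-efficiency component's
#' area over the total area.
#'
#' @param trajs list of trajectory data frames (or the output of
#'   [simulate_fret_trajectories()]).
#' @param n_bins histogram bins (default 50).
#' @return A `fret_histogram_fit`: `mean_folded`, `mean_unfolded`,
#'   `sd_folded`, `sd_unfolded`, `area_folded`, `area_unfolded` (frame
#'   counts), `fraction_unfolded`, `flags`, plus the histogram.
#' @export
fit_fret_histogram <- function(trajs, n_bins = 50) {
  e <- unlist(pool_efficiencies(trajs))
  e <- e[is.finite(e)]
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(e, breaks = breaks, plot = FALSE)
  dat <- data.frame(x = h$mids, y = h$counts)
  bw <- diff(breaks)[1]
  km <- tryCatch(
    stats::kmeans(e, centers = matrix(stats::quantile(e, c(0.15, 0.85)), 2L)),
    error = function(err) NULL)
  if (is.null(km)) km <- list(centers = matrix(range(e), 2L),
                              cluster = 1L + (e > mean(e)))
  mu0 <- sort(km$centers[, 1])
  sd0 <- pmax(vapply(1:2, function(k)
    stats::sd(e[km$cluster == order(km$centers[, 1])[k]]), 0), 0.02)
  a0 <- pmax(vapply(1:2, function(k)
    sum(km$cluster == order(km$centers[, 1])[k]) * bw /
      (sd0[k] * sqrt(2 * pi)), 1), 1)
  flags <- character(0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        a2 * exp(-(x - m2)^2 / (2 * s2^2)),
      data = dat,
      start = list(a1 = unname(a0[1]), m1 = unname(mu0[1]), s1 = unname(sd0[1]),
                   a2 = unname(a0[2]), m2 = unname(mu0[2]), s2 = unname(sd0[2])),
      lower = c(0, 0, 0.005, 0, 0, 0.005),
      upper = c(Inf, 1, 0.5, Inf, 1, 0.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(err) NULL)
  if (is.null(fit)) {
    # single-mode fallback: one Gaussian, collapsed-component flag
    flags <- c(flags, "collapsed_component")
    m <- mean(e); s <- stats::sd(e)
    area <- length(e)
    unf <- as.numeric(m < 0.5)
    return(structure(list(
      mean_folded = if (unf) NA_real_ else m,
      mean_unfolded = if (unf) m else NA_real_,
      sd_folded = if (unf) NA_real_ else s,
      sd_unfolded = if (unf) s else NA_real_,
      area_folded = area * (1 - unf), area_unfolded = area * unf,
      fraction_unfolded = unf, flags = flags, histogram = h
    ), class = "fret_histogram_fit"))
  }
  p <- stats::coef(fit)
  comp <- if (p[["m1"]] <= p[["m2"]]) c(low = 1L, high = 2L) else c(low = 2L, high = 1L)
  g <- function(i, nm) p[[paste0(nm, i)]]
  area <- function(i) g(i, "a") * g(i, "s") * sqrt(2 * pi) / bw  # frames
  a_low <- area(comp[["low"]]); a_high <- area(comp[["high"]])
  fraction <- a_low / (a_low + a_high)
  mean_folded <- g(comp[["high"]], "m"); mean_unfolded <- g(comp[["low"]], "m")
  sd_folded <- g(comp[["high"]], "s"); sd_unfolded <- g(comp[["low"]], "s")
  if (abs(g(1, "m") - g(2, "m")) < (g(1, "s") + g(2, "s")) / 2 ||
      min(a_low, a_high) / (a_low + a_high) < 1e-3) {
    # both Gaussians model one population: attribute the whole mass to the
    # side of the efficiency range its pooled mean falls on
    flags <- c(flags, "collapsed_component")
    pooled <- (a_low * mean_unfolded + a_high * mean_folded) / (a_low + a_high)
    if (pooled < 0.5) {
      fraction <- 1; mean_unfolded <- pooled; mean_folded <- NA_real_
      sd_folded <- NA_real_
    } else {
      fraction <- 0; mean_folded <- pooled; mean_unfolded <- NA_real_
      sd_unfolded <- NA_real_
    }
  }
  structure(list(
    mean_folded = mean_folded, mean_unfolded = mean_unfolded,
    sd_folded = sd_folded, sd_unfolded = sd_unfolded,
    area_folded = a_high, area_unfolded = a_low,
    fraction_unfolded = fraction,
    flags = flags, histogram = h, fit = fit
  ), class = "fret_histogram_fit")
}

#' @export
print.fret_histogram_fit <- function(x, ...) {
  cat(sprintf(
    "<fret_histogram_fit> folded E = %.3f (sd %.3f), unfolded E = %.3f (sd %.3f), unfolded fraction = %.3f%s\n",
    x$mean_folded, x$sd_folded, x$mean_unfolded, x$sd_unfolded,
    x$fraction_unfolded,
    if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Two-state idealization of FRET efficiency series
#'
#' Fits a two-state Gaussian-emission hidden Markov model to the pooled
#' efficiency series by expectation-maximization (Baum-Welch) and returns
#' the most likely (Viterbi) state path per trajectory. State 1 is the
#' high-efficiency (folded) state, state 2 the low-efficiency (unfolded)
#' state. Initialization from the efficiency histogram's two modes; if EM
#' fails to converge the series are thresholded at the midpoint between the
#' initial means and the result is flagged.
#'
#' @param e a numeric efficiency vector, a list of such vectors, or
#'   trajectories accepted by [fret_efficiency()]. Series must have at
#'   least 10 frames. `NA` frames are treated as missing emissions.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return An `fret_idealization`: `paths` (list of integer vectors,
#'   1 = folded, 2 = unfolded, `NA` at masked frames), `means`, `sds`,
#'   `transition` (2 x 2 per-frame matrix), `logLik`, `flags`.
#' @export
idealize_two_state <- function(e, max_iter = 100, tol = 1e-8) {
  if (is.data.frame(e) || (is.list(e) && !is.null(e$trajectories)))
    e <- pool_efficiencies(e)
  if (!is.list(e)) e <- list(e)
  if (any(vapply(e, length, 1L) < 10)) stop("each series needs >= 10 frames")
  pool <- unlist(e); pool <- pool[is.finite(pool)]
  if (stats::sd(pool) < 1e-6) {
    # constant series: a single state, zero transitions
    side <- if (mean(pool) >= 0.5) 1L else 2L
    paths <- lapply(e, function(x) ifelse(is.na(x), NA_integer_, side))
    return(structure(list(paths = paths,
                          means = c(mean(pool), mean(pool)),
                          sds = c(0, 0), transition = diag(2),
                          initial = c(side == 1L, side == 2L) * 1,
                          logLik = NA_real_, converged = TRUE,
                          flags = "single_state"),
                     class = "fret_idealization"))
  }
  km <- stats::kmeans(pool, centers = matrix(stats::quantile(pool, c(0.85, 0.15)), 2L))
  ord <- order(km$centers[, 1], decreasing = TRUE)   # state 1 = high E
  mu <- km$centers[ord, 1]
  sg <- pmax(vapply(1:2, function(k) stats::sd(pool[km$cluster == ord[k]]), 0),
             0.01)
  P <- matrix(c(0.95, 0.05, 0.05, 0.95), 2L, byrow = TRUE)
  pi0 <- c(0.5, 0.5)
  Tmax <- max(vapply(e, length, 1L))
  N <- length(e)
  E <- matrix(NA_real_, Tmax, N)
  for (n in seq_len(N)) E[seq_along(e[[n]]), n] <- e[[n]]
  len <- vapply(e, length, 1L)
  alive <- outer(seq_len(Tmax), len, "<=")

  emis <- function(mu, sg) {
    B1 <- stats::dnorm(E, mu[1], sg[1]); B2 <- stats::dnorm(E, mu[2], sg[2])
    B1[is.na(B1)] <- 1; B2[is.na(B2)] <- 1
    B1[!alive] <- 1; B2[!alive] <- 1
    list(pmax(B1, 1e-300), pmax(B2, 1e-300))
  }

  flags <- character(0)
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    B <- emis(mu, sg)
    # scaled forward
    a1 <- matrix(0, Tmax, N); a2 <- matrix(0, Tmax, N)
    cs <- matrix(1, Tmax, N)
    a1[1, ] <- pi0[1] * B[[1]][1, ]; a2[1, ] <- pi0[2] * B[[2]][1, ]
    cs[1, ] <- a1[1, ] + a2[1, ]
    a1[1, ] <- a1[1, ] / cs[1, ]; a2[1, ] <- a2[1, ] / cs[1, ]
    for (t in 2:Tmax) {
      f1 <- (a1[t - 1, ] * P[1, 1] + a2[t - 1, ] * P[2, 1]) * B[[1]][t, ]
      f2 <- (a1[t - 1, ] * P[1, 2] + a2[t - 1, ] * P[2, 2]) * B[[2]][t, ]
      cs[t, ] <- f1 + f2
      a1[t, ] <- f1 / cs[t, ]; a2[t, ] <- f2 / cs[t, ]
    }
    ll <- sum(log(cs[alive]))
    # backward
    b1 <- matrix(1, Tmax, N); b2 <- matrix(1, Tmax, N)
    x11 <- x12 <- x21 <- x22 <- 0
    g1 <- matrix(0, Tmax, N); g2 <- matrix(0, Tmax, N)
    g1[Tmax, ] <- a1[Tmax, ]; g2[Tmax, ] <- a2[Tmax, ]
    for (t in (Tmax - 1):1) {
      e1 <- B[[1]][t + 1, ] * b1[t + 1, ] / cs[t + 1, ]
      e2 <- B[[2]][t + 1, ] * b2[t + 1, ] / cs[t + 1, ]
      b1[t, ] <- P[1, 1] * e1 + P[1, 2] * e2
      b2[t, ] <- P[2, 1] * e1 + P[2, 2] * e2
      g1[t, ] <- a1[t, ] * b1[t, ]; g2[t, ] <- a2[t, ] * b2[t, ]
      w <- alive[t + 1, ]
      x11 <- x11 + sum((a1[t, ] * P[1, 1] * e1)[w])
      x12 <- x12 + sum((a1[t, ] * P[1, 2] * e2)[w])
      x21 <- x21 + sum((a2[t, ] * P[2, 1] * e1)[w])
      x22 <- x22 + sum((a2[t, ] * P[2, 2] * e2)[w])
    }
    obs <- alive & !is.na(E)
    W1 <- g1 * obs; W2 <- g2 * obs
    mu_new <- c(sum(W1 * E, na.rm = TRUE) / sum(W1),
                sum(W2 * E, na.rm = TRUE) / sum(W2))
    sg_new <- c(sqrt(sum(W1 * (E - mu_new[1])^2, na.rm = TRUE) / sum(W1)),
                sqrt(sum(W2 * (E - mu_new[2])^2, na.rm = TRUE) / sum(W2)))
    sg_new <- pmax(sg_new, 1e-4)
    P_new <- rbind(c(x11, x12) / (x11 + x12), c(x21, x22) / (x21 + x22))
    pi_new <- c(mean(g1[1, ]), mean(g2[1, ]))
    if (any(!is.finite(c(mu_new, sg_new, P_new, pi_new)))) {
      flags <- c(flags, "em_failed_threshold_fallback")
      break
    }
    mu <- mu_new; sg <- sg_new; P <- P_new; pi0 <- pi_new / sum(pi_new)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old) + 1e-12) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (mu[1] < mu[2]) {   # keep state 1 = high-E folded
    mu <- rev(mu); sg <- rev(sg); pi0 <- rev(pi0)
    P <- P[2:1, 2:1]
  }

  if ("em_failed_threshold_fallback" %in% flags) {
    mid <- mean(mu)
    paths <- lapply(e, function(x) ifelse(is.na(x), NA_integer_,
                                          ifelse(x >= mid, 1L, 2L)))
  } else {
    paths <- lapply(e, function(x) viterbi_two_state(x, mu, sg, P, pi0))
  }
  structure(list(paths = paths, means = mu, sds = sg, transition = P,
                 initial = pi0, logLik = ll_old, converged = converged,
                 flags = flags),
            class = "fret_idealization")
}

viterbi_two_state <- function(x, mu, sg, P, pi0) {
  Tn <- length(x)
  b1 <- log(pmax(stats::dnorm(x, mu[1], sg[1]), 1e-300))
  b2 <- log(pmax(stats::dnorm(x, mu[2], sg[2]), 1e-300))
  b1[is.na(x)] <- 0; b2[is.na(x)] <- 0
  lP <- log(pmax(P, 1e-300))
  d1 <- numeric(Tn); d2 <- numeric(Tn)
  p1 <- integer(Tn); p2 <- integer(Tn)
  d1[1] <- log(max(pi0[1], 1e-300)) + b1[1]
  d2[1] <- log(max(pi0[2], 1e-300)) + b2[1]
  for (t in 2:Tn) {
    c11 <- d1[t - 1] + lP[1, 1]; c21 <- d2[t - 1] + lP[2, 1]
    c12 <- d1[t - 1] + lP[1, 2]; c22 <- d2[t - 1] + lP[2, 2]
    if (c11 >= c21) { d1[t] <- c11 + b1[t]; p1[t] <- 1L }
    else            { d1[t] <- c21 + b1[t]; p1[t] <- 2L }
    if (c12 >= c22) { d2[t] <- c12 + b2[t]; p2[t] <- 1L }
    else            { d2[t] <- c22 + b2[t]; p2[t] <- 2L }
  }
  s <- integer(Tn)
  s[Tn] <- if (d1[Tn] >= d2[Tn]) 1L else 2L
  for (t in (Tn - 1):1) s[t] <- if (s[t + 1] == 1L) p1[t + 1] else p2[t + 1]
  s[is.na(x)] <- NA_integer_
  s
}

#' Maximum-likelihood exponential rate from dwell times
#'
#' @param dwells dwell durations (seconds).
#' @return List with `k` (s^-1), `sd` (`k/sqrt(n)`), `n`, `flags`.
#' @export
fit_exponential_rate <- function(dwells) {
  dwells <- dwells[is.finite(dwells) & dwells > 0]
  n <- length(dwells)
  if (n == 0) stop("no dwells")
  flags <- character(0)
  if (stats::sd(dwells) < 1e-12)
    flags <- c(flags, "degenerate_dwell_distribution")
  k <- 1 / mean(dwells)
  list(k = k, sd = k / sqrt(n), n = n, flags = flags)
}

#' Fold/unfold rates from idealized state paths
#'
#' Extracts per-state dwell times from two-state paths (first and last dwell
#' of every trajectory censored), and fits each state's dwell set with a
#' single-exponential maximum-likelihood rate: `k_unfold` from folded-state
#' dwells, `k_fold` from unfolded-state dwells. The reported sd is the
#' information-matrix standard error `k/sqrt(n)`.
#'
#' @param paths list of integer state paths (1 = folded, 2 = unfolded), or a
#'   `fret_idealization`.
#' @param frame_time frame duration in seconds (e.g. 0.03).
#' @param min_dwells minimum complete dwells required per state (default 10).
#' @return A `rate_fit`: `k_unfold`, `k_unfold_sd`, `k_fold`, `k_fold_sd`,
#'   `n_dwells` (per state), `flags`.
#' @export
fit_rates <- function(paths, frame_time, min_dwells = 10) {
  if (inherits(paths, "fret_idealization")) paths <- paths$paths
  stop_if_not_number(frame_time, "frame_time", positive = TRUE)
  dw <- list(`1` = numeric(0), `2` = numeric(0))
  for (p in paths) {
    p <- p[!is.na(p)]
    if (length(p) < 3) next
    r <- rle(p)
    if (length(r$lengths) <= 2) next
    keep <- 2:(length(r$lengths) - 1L)   # censor first and last dwell
    for (i in keep) {
      s <- as.character(r$values[i])
      dw[[s]] <- c(dw[[s]], r$lengths[i] * frame_time)
    }
  }
  for (s in c("1", "2")) {
    if (length(dw[[s]]) < min_dwells)
      stop(sprintf("too few complete dwells in the %s state (%d < %d)",
                   if (s == "1") "folded" else "unfolded",
                   length(dw[[s]]), min_dwells))
  }
  fu <- fit_exponential_rate(dw[["1"]])   # leaving folded -> k_unfold
  ff <- fit_exponential_rate(dw[["2"]])   # leaving unfolded -> k_fold
  structure(list(k_unfold = fu$k, k_unfold_sd = fu$sd,
                 k_fold = ff$k, k_fold_sd = ff$sd,
                 n_dwells = c(folded = fu$n, unfolded = ff$n),
                 flags = c(fu$flags, ff$flags)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_fit> k_unfold = %.3g +/- %.2g s^-1 (n=%d), k_fold = %.3g +/- %.2g s^-1 (n=%d)\n",
    x$k_unfold, x$k_unfold_sd, x$n_dwells[["folded"]],
    x$k_fold, x$k_fold_sd, x$n_dwells[["unfolded"]]))
  invisible(x)
}
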