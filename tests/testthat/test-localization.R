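test_that("a clean centred emitter is localized at its true position", {
  cal <- camera_calibration(matrix(100, 15, 15), matrix(2, 15, 15),
                            matrix(1e-6, 15, 15))
  # near-noiseless: huge photon count dominates, read noise negligible
  em <- data.frame(x = 7.5, y = 7.5, photons = 2e5)
  st <- simulate_frames(em, cal, psf_sigma = 1.3, background = 1,
                        n_frames = 1, seed = 1)
  # disable the misfit filter: at this photon count the 7x7 window's PSF
  # tail truncation dominates the deviance while leaving position unbiased
  loc <- localize_stack(st, psf_fwhm = 1.3 * 2 * sqrt(2 * log(2)),
                        max_deviance = Inf)
  expect_equal(nrow(loc), 1L)
  expect_lt(abs(loc$x_nm - 750), 0.5)
  expect_lt(abs(loc$y_nm - 750), 0.5)
})

test_that("CRLB agrees with a numerically differentiated Fisher information", {
  cal <- camera_calibration(matrix(100, 15, 15), matrix(2, 15, 15),
                            matrix(9, 15, 15))
  sigma_px <- 1.3
  em <- data.frame(x = 7.4, y = 7.6, photons = 5000)
  st <- simulate_frames(em, cal, psf_sigma = sigma_px, background = 5,
                        n_frames = 30, seed = 2)
  loc <- localize_stack(st, psf_fwhm = sigma_px * 2 * sqrt(2 * log(2)))
  expect_gt(nrow(loc), 25)

  # oracle: Fisher information of the variance-offset Poisson model at the
  # truth, Hessian of E[nll] via numeric differentiation of mu
  v_e <- 9 / 4
  mu_of <- function(th) {
    ex <- pnorm(1:7, th[1], sigma_px) - pnorm(0:6, th[1], sigma_px)
    ey <- pnorm(1:7, th[2], sigma_px) - pnorm(0:6, th[2], sigma_px)
    th[4] + th[3] * outer(ey, ex)
  }
  th0 <- c(3.4, 3.6, 5000, 5)   # window-local truth (candidate pixel (8, 8))
  h <- 1e-5
  grads <- lapply(1:4, function(k) {
    dp <- dm <- th0
    dp[k] <- dp[k] + h * max(abs(th0[k]), 1)
    dm[k] <- dm[k] - h * max(abs(th0[k]), 1)
    (mu_of(dp) - mu_of(dm)) / (2 * h * max(abs(th0[k]), 1))
  })
  mu <- mu_of(th0)
  FI <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    FI[a, b] <- sum(grads[[a]] * grads[[b]] / (mu + v_e))
  crlb_xy_oracle <- sqrt(diag(solve(FI))[1:2]) * 100   # nm
  pkg_crlb <- sqrt(c(mean(loc$crlb_x_nm2), mean(loc$crlb_y_nm2)))
  expect_equal(unname(pkg_crlb), unname(crlb_xy_oracle), tolerance = 0.1)
})

test_that("pure-background frames produce no localizations", {
  cal <- simulate_calibration(20, 20, seed = 3)
  none <- data.frame(x = numeric(0), y = numeric(0), photons = numeric(0))
  st <- simulate_frames(none, cal, background = 10, n_frames = 5, seed = 4)
  loc <- localize_stack(st, psf_fwhm = 3)
  expect_equal(nrow(loc), 0L)
})

test_that("blink merging follows the inverse-variance worked example", {
  t <- data.frame(channel = 1L, x_nm = c(0, 30), y_nm = c(0, 0),
                  frame = c(5L, 6L), photons = c(1000, 800), background = 0,
                  precision_nm = c(10, 20), crlb_x_nm2 = c(100, 400),
                  crlb_y_nm2 = c(100, 400), multiplicity = 1L)
  m <- merge_blinking(t)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x_nm, 6.0)            # (0/100 + 30/400) / (1/100 + 1/400)
  expect_equal(m$crlb_x_nm2, 80)       # 1 / (1/100 + 1/400)
  expect_equal(m$multiplicity, 2L)
  expect_equal(m$photons, 1800)

  # a frame gap breaks the chain
  t2 <- t; t2$frame <- c(5L, 7L)
  expect_equal(nrow(merge_blinking(t2)), 2L)

  # single record unchanged
  one <- merge_blinking(t[1, ])
  expect_equal(one$x_nm, 0)
  expect_equal(one$multiplicity, 1L)

  # empty table passes through
  expect_equal(nrow(merge_blinking(t[0, ])), 0L)
})

test_that("merging is idempotent and conserves multiplicity on synthetic blinks", {
  set.seed(6)
  rows <- list()
  for (mol in 1:40) {
    x <- runif(1, 0, 5000); y <- runif(1, 0, 5000)
    f0 <- sample(0:50, 1); len <- 1 + rpois(1, 2)
    for (k in seq_len(len)) {
      rows[[length(rows) + 1]] <- data.frame(
        channel = 1L, x_nm = x + rnorm(1, 0, 8), y_nm = y + rnorm(1, 0, 8),
        frame = f0 + k - 1L, photons = 1000, background = 0,
        precision_nm = 8, crlb_x_nm2 = 64, crlb_y_nm2 = 64, multiplicity = 1L)
    }
  }
  tab <- do.call(rbind, rows)
  m1 <- merge_blinking(tab)
  m2 <- merge_blinking(m1)
  expect_lte(nrow(m1), nrow(tab))
  expect_equal(sum(m1$multiplicity), nrow(tab))
  expect_equal(nrow(m2), nrow(m1))
  expect_equal(m2$x_nm, m1$x_nm)
  expect_equal(sum(m2$multiplicity), nrow(tab))
})

test_that("precision distributions are recovered by the skew-Gaussian fit", {
  set.seed(1)
  x <- rsn_oracle(5000, 10, 3, 4)
  f <- fit_precision_distribution(x)
  expect_equal(f$location, 10, tolerance = 0.1)
  expect_equal(f$scale, 3, tolerance = 0.1)
  expect_equal(f$shape, 4, tolerance = 0.2)

  set.seed(2)
  fg <- fit_precision_distribution(rnorm(5000, 15, 3))
  expect_lt(abs(fg$shape), 1)          # symmetric input: shape ~ 0

  expect_error(fit_precision_distribution(rep(10, 100)), "degenerate")
  expect_error(fit_precision_distribution(rnorm(20, 10, 1)), "at least 50")
})

test_that("rendering conserves mass and is linear", {
  roi <- c(0, 2000, 0, 2000)
  f1 <- localization_field(1000, 1000, roi)
  img1 <- render_image(f1, 10, 10)
  expect_equal(sum(img1), 1, tolerance = 1e-6)

  f2 <- localization_field(c(1000, 1000), c(1000, 1000), roi)
  img2 <- render_image(f2, 10, 10)
  expect_equal(img2, 2 * img1, tolerance = 1e-12)

  corner <- render_image(localization_field(2, 2, roi), 10, 10)
  expect_lt(sum(corner), 1)            # truncation at the canvas edge

  empty <- render_image(localization_field(numeric(0), numeric(0), roi))
  expect_true(all(empty == 0))
})
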