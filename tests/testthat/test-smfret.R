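test_that("frame-wise efficiency is acceptor over total, clipped and masked", {
  tr <- data.frame(frame = 0:2, donor = c(30, 50, 100), acceptor = c(70, 50, 0))
  e <- fret_efficiency(tr)
  expect_equal(e, c(0.7, 0.5, 0))
  # all-zero frame masked with a warning; dark frames masked
  tr2 <- data.frame(frame = 0:3, donor = c(100, 0, 100, 2),
                    acceptor = c(100, 0, 100, 3))
  expect_warning(e2 <- fret_efficiency(tr2), "masked")
  expect_true(is.na(e2[2]))
  expect_true(is.na(e2[4]))   # 5 photons < 10% of median total
})

test_that("two-Gaussian histogram decomposition recovers planted mixtures", {
  # 50/50 frame mixture at well-separated means
  spec <- fret_sim_spec(n_traj = 120, n_frames = 400, k_unfold = 1, k_fold = 1,
                        e_folded = 0.70, e_unfolded = 0.25,
                        total_intensity = 1000, noise_sigma = 70, seed = 81)
  sim <- simulate_fret_trajectories(spec)
  h <- fit_fret_histogram(sim)
  expect_equal(h$fraction_unfolded, 0.5, tolerance = 0.06)  # abs 0.03
  expect_lt(abs(h$mean_folded - 0.70), 0.02)
  expect_lt(abs(h$mean_unfolded - 0.25), 0.02)

  # independent cross-check of the component means with a Gaussian mixture EM
  withr::local_package("mclust")
  e <- unlist(lapply(sim$trajectories, fret_efficiency))
  mc <- Mclust(e[is.finite(e)], G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(max(mc$parameters$mean) - h$mean_folded), 0.01)
  expect_lt(abs(min(mc$parameters$mean) - h$mean_unfolded), 0.01)

  # all frames in the low-E state: unfolded fraction ~ 1
  spec1 <- fret_sim_spec(n_traj = 30, n_frames = 200, k_unfold = 50,
                         k_fold = 0.001, total_intensity = 1000,
                         noise_sigma = 70, seed = 82)
  sim1 <- simulate_fret_trajectories(spec1)
  h1 <- fit_fret_histogram(sim1)
  expect_gt(h1$fraction_unfolded, 0.95)
})

test_that("idealization recovers state paths and handles degenerate input", {
  # noiseless alternating segments: exact recovery
  e_clean <- rep(c(rep(0.7, 25), rep(0.25, 25)), 8)
  id <- idealize_two_state(list(e_clean, e_clean))
  truth <- rep(c(rep(1L, 25), rep(2L, 25)), 8)
  expect_equal(id$paths[[1]], truth)

  # noisy two-state data: >= 95% frame-wise accuracy
  spec <- fret_sim_spec(n_traj = 40, n_frames = 400, k_unfold = 1.5,
                        k_fold = 1.5, total_intensity = 1000,
                        noise_sigma = 70, seed = 91)
  sim <- simulate_fret_trajectories(spec)
  id2 <- idealize_two_state(sim)
  acc <- mean(mapply(function(p, s) mean(p == s, na.rm = TRUE),
                     id2$paths, sim$states))
  expect_gte(acc, 0.95)
  expect_lt(abs(id2$means[1] - 0.7), 0.02)
  expect_lt(abs(id2$means[2] - 0.25), 0.02)

  # constant series: one state, zero transitions
  idc <- idealize_two_state(rep(0.68, 200))
  expect_true(all(idc$paths[[1]] == 1L))
  expect_true("single_state" %in% idc$flags)

  expect_error(idealize_two_state(c(0.5, 0.6)), ">= 10")
})

test_that("exponential dwell fitting matches its sampling distribution", {
  set.seed(101)
  dw <- rexp(500, rate = 2)
  f <- fit_exponential_rate(dw)
  expect_equal(f$k, 2, tolerance = 0.15)          # se = k/sqrt(n) ~ 0.09
  expect_equal(f$sd, f$k / sqrt(500), tolerance = 1e-12)
  fd <- fit_exponential_rate(rep(0.5, 20))
  expect_true("degenerate_dwell_distribution" %in% fd$flags)
})

test_that("simulate -> idealize -> fit recovers rates across a grid", {
  for (rates in list(c(0.5, 1.5), c(1, 1))) {
    spec <- fret_sim_spec(n_traj = 120, n_frames = 800,
                          k_unfold = rates[1], k_fold = rates[2],
                          total_intensity = 1000, noise_sigma = 70,
                          seed = 110 + round(10 * rates[1]))
    sim <- simulate_fret_trajectories(spec)
    id <- idealize_two_state(sim)
    r <- fit_rates(id, spec$frame_time)
    expect_lt(abs(r$k_unfold - rates[1]) / rates[1], 0.15)
    expect_lt(abs(r$k_fold - rates[2]) / rates[2], 0.15)
  }
})

test_that("rate fitting censors edge dwells and validates dwell counts", {
  # path with only two dwells contributes nothing (all censored)
  p <- c(rep(1L, 50), rep(2L, 50))
  expect_error(fit_rates(list(p), 0.03), "too few complete dwells")

  # histogram unfolded fraction ~ idealized path occupancy
  spec <- fret_sim_spec(n_traj = 80, n_frames = 400, k_unfold = 1, k_fold = 2,
                        total_intensity = 1000, noise_sigma = 70, seed = 120)
  sim <- simulate_fret_trajectories(spec)
  h <- fit_fret_histogram(sim)
  id <- idealize_two_state(sim)
  occ <- mean(unlist(id$paths) == 2L, na.rm = TRUE)
  expect_lt(abs(h$fraction_unfolded - occ), 0.05)
})
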