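test_that("frame simulator reproduces the sCMOS pixel model", {
  cal <- simulate_calibration(9, 9, seed = 1)
  none <- data.frame(x = numeric(0), y = numeric(0), photons = numeric(0))

  # no emitters, no background, no read noise -> pixels equal the offset map
  cal0 <- camera_calibration(cal$offset, cal$gain, cal$read_var * 0)
  st <- simulate_frames(none, cal0, background = 0, n_frames = 2, seed = 2)
  expect_equal(st$frames[1, , ], cal0$offset, tolerance = 1e-12)

  # doubling the gain doubles the background signal above offset
  st1 <- simulate_frames(none, cal, background = 20, n_frames = 40, seed = 3)
  cal2 <- camera_calibration(cal$offset, cal$gain * 2, cal$read_var)
  st2 <- simulate_frames(none, cal2, background = 20, n_frames = 40, seed = 3)
  m1 <- mean(apply(st1$frames, 1, function(f) mean(f - cal$offset)))
  m2 <- mean(apply(st2$frames, 1, function(f) mean(f - cal$offset)))
  expect_equal(m2 / m1, 2, tolerance = 1e-3)  # same seed, same Poisson draws

  # many-frame average recovers the analytic PSF-integral image
  em <- data.frame(x = 4.3, y = 4.7, photons = 5000)
  st <- simulate_frames(em, cal, psf_sigma = 1.2, background = 0,
                        n_frames = 400, seed = 4)
  avg <- apply(st$frames, c(2, 3), mean)
  recovered <- (avg - cal$offset) / cal$gain
  oracle <- expected_psf_image(4.3, 4.7, 5000, 1.2, 9, 9)
  expect_lt(max(abs(recovered - oracle)) / max(oracle), 0.05)

  # error paths
  expect_error(simulate_frames(data.frame(x = 20, y = 2, photons = 100), cal),
               "inside the frame")
  expect_error(camera_calibration(cal$offset, cal$gain * 0, cal$read_var),
               "gain")
})

test_that("CSR point fields follow the homogeneous Poisson process", {
  counts <- vapply(1:40, function(s)
    nrow(generate_point_field(100, 6000, seed = s)), 1L)
  # mean count = density x area = 3600; 40 replicates, sem = 60/sqrt(40)
  expect_lt(abs(mean(counts) - 3600), 4 * 60 / sqrt(40) + 1)
  expect_equal(nrow(generate_point_field(0, 6000, seed = 1)), 0L)
  expect_error(generate_point_field(-5, 6000), ">= 0")

  f1 <- generate_point_field(50, 6000, seed = 7)
  f2 <- generate_point_field(50, 6000, seed = 7)
  f3 <- generate_point_field(50, 6000, seed = 8)
  expect_identical(f1$x_nm, f2$x_nm)         # seed contract
  expect_false(isTRUE(all.equal(f1$x_nm[1], f3$x_nm[1])))
})

test_that("triplet scenes plant the requested geometry with exact ground truth", {
  expect_error(scene_spec(triplet_geometry = c(100, 100, 300)),
               "triangle inequality")

  # noiseless construction: vertex distances equal the geometry exactly
  sp <- scene_spec(n_triplets = 10, site_sigma = 0, localization_sigma = 0,
                   background_density = c(0, 0, 0),
                   detection_efficiency = c(1, 1, 1),
                   triplet_geometry = c(100, 100, 100), seed = 5)
  sc <- generate_triplet_scene(sp)
  s <- sc$sites
  for (k in 1:10) {
    v <- s[s$triplet == k, ]
    d12 <- sqrt(diff(v$site_x[1:2])^2 + diff(v$site_y[1:2])^2)
    d13 <- sqrt((v$site_x[3] - v$site_x[1])^2 + (v$site_y[3] - v$site_y[1])^2)
    expect_equal(c(d12, d13), c(100, 100), tolerance = 1e-9)
  }

  # zero detection efficiency in channel 3 leaves only background there
  sp0 <- scene_spec(n_triplets = 20, detection_efficiency = c(0.8, 0.8, 0),
                    background_density = c(20, 20, 20), seed = 6)
  sc0 <- generate_triplet_scene(sp0)
  expect_true(all(sc0$sites$n_detected[sc0$sites$channel == 3] == 0))
  # channel-3 count is then Poisson(20 * 36); check a loose 5-sigma band
  expect_lt(abs(nrow(sc0$fields[[3]]) - 720), 5 * sqrt(720))

  # planted scene passed to the brute-force counter at the true geometry
  sp2 <- scene_spec(n_triplets = 50, seed = 2)
  sc2 <- generate_triplet_scene(sp2)
  n <- brute_force_triplets(sc2$fields[[1]], sc2$fields[[2]], sc2$fields[[3]],
                            c(100, 100, 100), 3 * sp2$site_sigma)
  expect_gte(n, 50)
})

test_that("two-state FRET simulator matches its Markov ground truth", {
  # stationary unfolded occupancy = k_unfold / (k_unfold + k_fold)
  spec <- fret_sim_spec(n_traj = 30, n_frames = 2000, k_unfold = 1, k_fold = 3,
                        seed = 9)
  sim <- simulate_fret_trajectories(spec)
  occ <- mean(unlist(sim$states) == 2L)
  expect_lt(abs(occ - 0.25), 0.02)

  # zero noise: frame-wise efficiency is exactly e_folded or e_unfolded
  spec0 <- fret_sim_spec(n_traj = 2, n_frames = 100, noise_sigma = 0, seed = 10)
  sim0 <- simulate_fret_trajectories(spec0)
  e <- fret_efficiency(sim0$trajectories[[1]])
  expect_true(all(abs(e - 0.7) < 1e-12 | abs(e - 0.25) < 1e-12))

  # ground-truth folded dwells are exponential with mean 1/k_unfold
  spec2 <- fret_sim_spec(n_traj = 60, n_frames = 800, k_unfold = 2, k_fold = 2,
                         seed = 11)
  sim2 <- simulate_fret_trajectories(spec2)
  dwells <- unlist(lapply(sim2$states, function(s) {
    r <- rle(s)
    if (length(r$lengths) <= 2) return(numeric(0))
    keep <- 2:(length(r$lengths) - 1)
    r$lengths[keep][r$values[keep] == 1L] * spec2$frame_time
  }))
  # discrete sampling at dt makes dwells geometric with the matched
  # per-frame leave probability; check mean and survival-curve linearity
  p_leave <- 2 * (1 - exp(-(2 + 2) * 0.03)) / (2 + 2)
  frames <- dwells / 0.03
  se <- stats::sd(frames) / sqrt(length(frames))
  expect_lt(abs(mean(frames) - 1 / p_leave), 4 * se)
  ks <- seq_len(stats::quantile(frames, 0.9))
  surv <- vapply(ks, function(k) mean(frames > k), numeric(1))
  fitlm <- stats::lm(log(surv) ~ ks)
  expect_gt(summary(fitlm)$r.squared, 0.98)
  expect_equal(unname(stats::coef(fitlm)[2]), log(1 - p_leave),
               tolerance = 0.1)

  expect_error(fret_sim_spec(e_folded = 1.2), "\\(0, 1\\)")
  expect_error(fret_sim_spec(e_folded = 0.3, e_unfolded = 0.5), "exceed")

  # seed determinism
  a <- simulate_fret_trajectories(fret_sim_spec(n_traj = 2, seed = 12))
  b <- simulate_fret_trajectories(fret_sim_spec(n_traj = 2, seed = 12))
  expect_identical(a$trajectories, b$trajectories)
})

test_that("scene generators are deterministic under a fixed seed", {
  sp <- scene_spec(n_triplets = 15, seed = 42)
  a <- generate_triplet_scene(sp)
  b <- generate_triplet_scene(sp)
  expect_identical(a$fields[[2]]$x_nm, b$fields[[2]]$x_nm)
  expect_identical(a$sites, b$sites)
  f1 <- generate_clustered_field(n_clusters = 30, seed = 3)
  f2 <- generate_clustered_field(n_clusters = 30, seed = 3)
  expect_identical(f1$x_nm, f2$x_nm)
})
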