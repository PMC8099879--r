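test_that("the third-side transform matches its printed worked examples", {
  expect_equal(tc_r3(100, 100, 120 * pi / 180), 100, tolerance = 1e-9)
  expect_equal(tc_r3(100, 100, 0), 200, tolerance = 1e-9)
})

test_that("independent CSR channels give a flat TC map", {
  f1 <- generate_point_field(20, 6000, seed = 11)
  f2 <- generate_point_field(20, 6000, seed = 12)
  f3 <- generate_point_field(20, 6000, seed = 13)
  m <- compute_tc_map(f1, f2, f3)
  nl <- tc_null_maps(f1, f2, f3, n_rand = 20, seed = 14)
  z <- tc_zscores(m, nl)
  expect_gt(mean(abs(z) <= 3, na.rm = TRUE), 0.99)
  expect_equal(nrow(find_tc_triplets(m, nl)), 0L)
})

test_that("planted equilateral triplets peak at the planted geometry", {
  sp <- scene_spec(n_triplets = 50, triplet_geometry = c(100, 100, 100),
                   background_density = c(20, 20, 20), seed = 2)
  sc <- generate_triplet_scene(sp)
  m <- compute_tc_map(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]])
  idx <- which(m$f == max(m$f, na.rm = TRUE), arr.ind = TRUE)
  peak <- c(m$r_centers[idx[1, 1]], m$r_centers[idx[1, 2]],
            m$r3_centers[idx[1, 3]])
  expect_true(all(abs(peak - 100) <= 20))

  nl <- tc_null_maps(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]],
                     n_rand = 20, seed = 3)
  z <- tc_zscores(m, nl)
  expect_gte(z[idx], 5)
  tr <- find_tc_triplets(m, nl)
  expect_gte(nrow(tr), 1L)
  expect_true(all(abs(c(tr$r1_nm[1], tr$r2_nm[1], tr$r3_nm[1]) - 100) <= 20))
})

test_that("a scalene planted geometry is recovered within one bin", {
  sp <- scene_spec(n_triplets = 60, triplet_geometry = c(100, 140, 100),
                   background_density = c(15, 15, 15), seed = 7)
  sc <- generate_triplet_scene(sp)
  m <- compute_tc_map(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]])
  nl <- tc_null_maps(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]],
                     n_rand = 20, seed = 8)
  tr <- find_tc_triplets(m, nl)
  expect_gte(nrow(tr), 1L)
  expect_true(all(abs(c(tr$r1_nm[1] - 100, tr$r2_nm[1] - 140,
                        tr$r3_nm[1] - 100)) <= 20))
})

test_that("null maps are seeded and statistically exchangeable on CSR input", {
  f1 <- generate_point_field(15, 6000, seed = 21)
  f2 <- generate_point_field(15, 6000, seed = 22)
  f3 <- generate_point_field(15, 6000, seed = 23)
  a <- tc_null_maps(f1, f2, f3, n_rand = 3, seed = 5)
  b <- tc_null_maps(f1, f2, f3, n_rand = 3, seed = 5)
  expect_identical(a[[2]]$f, b[[2]]$f)
  c <- tc_null_maps(f1, f2, f3, n_rand = 3, seed = 6)
  expect_false(identical(a[[1]]$f, c[[1]]$f))
  expect_error(tc_null_maps(f1, f2, f3, n_rand = 1), ">= 2")
})

test_that("channel-2/3 exchange transposes the collapsed TC grid", {
  sp <- scene_spec(n_triplets = 25, triplet_geometry = c(80, 120, 140),
                   seed = 31)
  sc <- generate_triplet_scene(sp)
  m23 <- compute_tc_map(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]])
  m32 <- compute_tc_map(sc$fields[[1]], sc$fields[[3]], sc$fields[[2]])
  f23 <- m23$f; f32 <- aperm(m32$f, c(2, 1, 3))
  ok <- is.finite(f23) & is.finite(f32)
  expect_gt(sum(ok), 100)
  expect_equal(f23[ok], f32[ok], tolerance = 1e-9)
})

test_that("TC excess scales linearly with planted triplet density", {
  # the normalized amplitude divides by the channel densities, which grow
  # with the planted count; the quantity linear in triplet density is the
  # unnormalized third-order moment f * rho1 * rho2 * rho3
  ladder <- c(15, 30, 60, 120)
  peaks <- vapply(seq_along(ladder), function(i) {
    sp <- scene_spec(n_triplets = ladder[i], seed = 40 + i,
                     background_density = c(15, 15, 15))
    sc <- generate_triplet_scene(sp)
    m <- compute_tc_map(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]])
    i1 <- which.min(abs(m$r_centers - 100))
    k <- which.min(abs(m$r3_centers - 100))
    # fixed planted cell (plus immediate neighbours in r3)
    max(m$f[i1, i1, max(1, k - 1):(k + 1)], na.rm = TRUE) * prod(m$rho_um2)
  }, numeric(1))
  fitlm <- stats::lm(peaks ~ ladder)
  r2 <- summary(fitlm)$r.squared
  expect_gt(r2, 0.9)
  expect_gt(stats::coef(fitlm)[2], 0)
})

test_that("conditional density reflects channel-3 site occupancy", {
  tri <- list(r1_nm = 90, r2_nm = 110, r3_nm = 110)
  c3 <- vapply(c(5, 10), function(mm) {
    sp <- scene_spec(n_triplets = 80, molecules_per_site = c(8, 8, mm),
                     seed = 7)
    sc <- generate_triplet_scene(sp)
    conditional_density(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]], tri)
  }, numeric(1))
  expect_lt(abs(c3[2] / c3[1] - 2), 0.5)   # doubling occupancy doubles C3

  # uniform channel-3 background cancels in the delta-rho construction
  c3b <- vapply(c(20, 40), function(bg) {
    sp <- scene_spec(n_triplets = 80, background_density = c(20, 20, bg),
                     seed = 8)
    sc <- generate_triplet_scene(sp)
    conditional_density(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]], tri)
  }, numeric(1))
  expect_lt(abs(c3b[2] / c3b[1] - 1), 0.25)

  # independent third channel: C3 near zero relative to the planted value
  sp <- scene_spec(n_triplets = 80, seed = 10)
  sc <- generate_triplet_scene(sp)
  f3 <- generate_point_field(50, 6000, seed = 9)
  c3i <- conditional_density(sc$fields[[1]], sc$fields[[2]], f3, tri)
  expect_lt(abs(c3i), 0.2 * c3[1])

  expect_error(
    conditional_density(sc$fields[[1]], sc$fields[[2]], sc$fields[[3]],
                        list(r1_nm = 50, r2_nm = 60, r3_nm = 200)),
    "triangle")
})

test_that("brute-force triplet counting is exact on constructed points", {
  roi <- c(0, 1000, 0, 1000)
  f1 <- localization_field(500, 500, roi)
  f2 <- localization_field(600, 500, roi)             # 100 from f1
  f3 <- localization_field(550, 500 + 50 * sqrt(3), roi)  # equilateral
  expect_equal(brute_force_triplets(f1, f2, f3, c(100, 100, 100), 1), 1L)
  expect_equal(brute_force_triplets(f1, f2, f3, c(100, 100, 100), 0.1), 1L)
  expect_equal(brute_force_triplets(f1, f2, f3, c(150, 100, 100), 1), 0L)
  empty <- localization_field(numeric(0), numeric(0), roi)
  expect_equal(brute_force_triplets(f1, f2, empty, c(100, 100, 100), 5), 0L)
})

test_that("triplet frequency is instances per reference pattern", {
  roi <- c(0, 1000, 0, 1000)
  f1 <- localization_field(500, 500, roi)
  f2 <- localization_field(600, 500, roi)
  f3 <- localization_field(550, 500 + 50 * sqrt(3), roi)
  tr <- data.frame(r1_nm = 100, r2_nm = 100, r3_nm = 100, f = 10, z = 6)
  fr <- triplet_frequency(tr, f1, f2, f3, reference_pattern_count = 20,
                          tolerance = 5)
  expect_equal(fr$frequency, 1 / 20)
  none <- tr[0, ]
  expect_equal(triplet_frequency(none, f1, f2, f3, 100)$frequency, 0)
  expect_error(triplet_frequency(tr, f1, f2, f3, 0), "> 0")
})
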