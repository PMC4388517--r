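test_that("Compton kinematics follow the closed form", {
  expect_equal(compton_energy(159, pi), 98.0, tolerance = 0.001)
  expect_equal(compton_energy(27.5, pi / 2), 26.1, tolerance = 0.004)
  expect_equal(compton_energy(c(10, 100, 528), 0), c(10, 100, 528))
  th <- seq(0, pi, length.out = 50)
  expect_true(all(compton_energy(159, th) <= 159))
  expect_error(compton_energy(-1, 0))
})

test_that("Klein-Nishina angle sampler matches the numerically integrated CDF", {
  set.seed(11)
  for (e in c(159, 27.5)) {
    th <- sample_kn_angle(e, 2e4)
    expect_true(all(th >= 0 & th <= pi))
    ks <- suppressWarnings(stats::ks.test(th, kn_angle_cdf_oracle(e)))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("low-energy limit of the angle sampler approaches Thomson scattering", {
  set.seed(12)
  cth <- cos(sample_kn_angle(0.1, 4e4))
  # Thomson density in cos(theta) is proportional to 1 + cos^2, symmetric
  expect_lt(abs(mean(cth)), 0.02)
  thomson_cdf <- function(q) (3 / 8) * ((q + q^3 / 3) - (-1 - 1 / 3)) / 1
  ks <- suppressWarnings(stats::ks.test(cth, thomson_cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("angle sampling is reproducible under a fixed seed", {
  set.seed(5); a <- sample_kn_angle(159, 100)
  set.seed(5); b <- sample_kn_angle(159, 100)
  expect_identical(a, b)
})

test_that("absorption-only escape follows Beer-Lambert from a centred point source", {
  ph <- sphere_phantom(1, activities = c(I123 = 1), material = "water",
                       source_radius_cm = 0.05, voxel_mm = 0.5)
  n <- 4e4
  set.seed(21)
  res <- transport_photons(ph, matrix(0, n, 3), rep(159, n), max_scatters = 0)
  p <- exp(-mu_total("water", 159) * 1)
  expect_equal(mean(res$escaped), p, tolerance = 3 * sqrt(p * (1 - p) / n) / p)
  expect_true(all(res$n_scatters == 0))
})

test_that("free paths in homogeneous water have the exponential mean 1/mu", {
  # a large slab so nearly all first flights end inside; absorption-only mode
  ph <- sphere_phantom(3, activities = c(I123 = 1), material = "water",
                       source_radius_cm = 0.1, voxel_mm = 1)
  # escape fraction from centre at radius 3 gives the integrated exponential law
  n <- 3e4
  set.seed(22)
  res <- transport_photons(ph, matrix(0, n, 3), rep(159, n), max_scatters = 0)
  p <- exp(-mu_total("water", 159) * 3)
  expect_equal(mean(res$escaped), p,
               tolerance = 3 * sqrt(p * (1 - p) / n) / p)
})

test_that("vacuum grids always escape with unchanged energy", {
  ph <- sphere_phantom(0.5, activities = c(I123 = 1), material = "vacuum",
                       voxel_mm = 0.5)
  set.seed(23)
  res <- transport_photons(ph, matrix(0, 100, 3), rep(159, 100))
  expect_true(all(res$escaped))
  expect_true(all(res$energy_kev == 159))
})

test_that("conservation and energy monotonicity hold with scattering on", {
  ph <- sphere_phantom(2, activities = c(I123 = 1), material = "water",
                       source_radius_cm = 0.1, voxel_mm = 1)
  set.seed(24)
  n <- 2e4
  res <- transport_photons(ph, matrix(0, n, 3), rep(159, n))
  expect_equal(nrow(res), n)  # escaped + absorbed = emitted
  expect_true(all(res$energy_kev <= 159 + 1e-9))
  expect_true(all(res$energy_kev[res$escaped & res$n_scatters == 0] == 159))
  expect_gt(sum(res$escaped & res$n_scatters > 0), 0)
})

test_that("max_scatters = 0 reduces transport to the absorption-only outcome law", {
  ph <- sphere_phantom(1.5, activities = c(I123 = 1), material = "water",
                       source_radius_cm = 0.1, voxel_mm = 1)
  set.seed(25)
  n <- 3e4
  res0 <- transport_photons(ph, matrix(0, n, 3), rep(100, n), max_scatters = 0)
  p <- exp(-mu_total("water", 100) * 1.5)
  expect_equal(mean(res0$escaped), p,
               tolerance = 3 * sqrt(p * (1 - p) / n) / p)
})

test_that("Woodcock tracking agrees with a ray-marching oracle on a 3-material grid", {
  ph <- toy_grid_phantom()
  set.seed(26)
  expected <- escape_fraction_oracle(ph, c(0.1, 0, 0), 80, n_dirs = 3000)
  n <- 3e4
  res <- transport_photons(ph, matrix(c(0.1, 0, 0), n, 3, byrow = TRUE),
                           rep(80, n), max_scatters = 0)
  se <- sqrt(expected * (1 - expected) / n)
  expect_equal(mean(res$escaped), expected, tolerance = 4 * se / expected)
})

test_that("transport is reproducible and rejects outside positions", {
  ph <- sphere_phantom(0.5, activities = c(I123 = 1), voxel_mm = 0.5)
  set.seed(9); a <- transport_photons(ph, matrix(0, 50, 3), rep(159, 50))
  set.seed(9); b <- transport_photons(ph, matrix(0, 50, 3), rep(159, 50))
  expect_identical(a, b)
  expect_error(transport_photons(ph, matrix(99, 1, 3), 159), "inside")
})

test_that("downscatter into the low window grows with water sphere size", {
  set.seed(27)
  frac_lo <- vapply(c(0.5, 3), function(r) {
    ph <- sphere_phantom(r, activities = c(I123 = 1), material = "water",
                         source_radius_cm = 0.3, voxel_mm = 1)
    n <- 5e4
    res <- transport_photons(ph, matrix(0, n, 3), rep(159, n))
    sum(res$escaped & res$energy_kev >= 25 & res$energy_kev < 45) / n
  }, numeric(1))
  expect_gte(frac_lo[2], frac_lo[1])
})
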