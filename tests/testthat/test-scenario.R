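small_sphere_cfg <- function(n_decays = 5000, n_reps = 2, seed = 1, ...) {
  ph <- sphere_phantom(0.5, activities = c(I123 = 200), material = "vacuum",
                       voxel_mm = 0.5)
  scenario_config(ph, spect_system("ideal4pi", blur = FALSE),
                  n_decays = c(I123 = n_decays), n_reps = n_reps,
                  seed = seed, ...)
}

test_that("the full pipeline is deterministic under a fixed seed", {
  a <- run_scenario(small_sphere_cfg(seed = 99))
  b <- run_scenario(small_sphere_cfg(seed = 99))
  expect_identical(a$counts, b$counts)
  c2 <- run_scenario(small_sphere_cfg(seed = 100))
  expect_false(identical(a$counts, c2$counts))
})

test_that("distinct seeds give statistically compatible summaries", {
  g1 <- glance(run_scenario(small_sphere_cfg(n_decays = 2e4, n_reps = 3,
                                             seed = 1)))
  g2 <- glance(run_scenario(small_sphere_cfg(n_decays = 2e4, n_reps = 3,
                                             seed = 2)))
  se <- sqrt(g1$LO_sd^2 + g2$LO_sd^2) / sqrt(3)
  expect_lt(abs(g1$LO_mean - g2$LO_mean), 5 * se)
})

test_that("tiny decay counts run and produce bounded counts", {
  res <- run_scenario(small_sphere_cfg(n_decays = 1, n_reps = 1))
  expect_true(all(res$counts$counts %in% c(0, 1)))
  ph <- sphere_phantom(0.5, activities = c(I123 = 200), material = "vacuum")
  expect_error(scenario_config(ph, n_decays = c(I123 = 0)), "n_decays")
})

test_that("decay bookkeeping converts activity and time; doubling 125I doubles LO125", {
  expect_equal(decays_from_activity(1), 9.99e5)
  expect_equal(decays_from_activity(200, decay_scale = 1), 200 * 9.99e7)
  ph <- sphere_phantom(0.5, activities = c(I123 = 1, I125 = 1),
                       material = "vacuum", voxel_mm = 0.5)
  run_lo125 <- function(n125, seed) {
    cfg <- scenario_config(ph, spect_system("ideal4pi", blur = TRUE),
                           n_decays = c(I123 = 1e4, I125 = n125),
                           n_reps = 1, seed = seed)
    window_totals(run_scenario(cfg)$counts)$LO125
  }
  lo1 <- run_lo125(2e4, 7)
  lo2 <- run_lo125(4e4, 8)
  # expected blurred low-window retention per 125I line (Gaussian CDF)
  s <- iodine_spectrum("I125")
  sig <- 0.28 * s$energy_kev / 2.35482
  p <- sum(s$intensity * (pnorm(45, s$energy_kev, sig) -
                            pnorm(25, s$energy_kev, sig)))
  expect_lt(abs(lo2 - 2 * lo1), 3 * sqrt(6e4 * p * (1 - p)))
})

test_that("ideal pure-123I scenario matches the emission-fraction closed form", {
  res <- run_scenario(small_sphere_cfg(n_decays = 5e4, n_reps = 2, seed = 3))
  est <- estimate_e123(res$counts)
  expect_equal(est$e123, 0.504 / 0.484, tolerance = 0.03)
  expect_equal(est$n_reps, 2)
})

test_that("condition ladder output has the expected schema", {
  lad <- sweep_imaging_conditions(n_decays = 2e4, n_reps = 2, seed = 4)
  expect_equal(nrow(lad), 6)
  expect_setequal(levels(lad$condition), c("ideal", "blur", "scatter"))
  expect_true(all(is.finite(lad$e123)))
})

test_that("sphere-size sweep rows carry per-rep scatter decompositions", {
  sw <- sweep_sphere_sizes(radii_cm = c(0.5, 1), n_decays = 2e4, n_reps = 2,
                           seed = 5, voxel_mm = 1)
  expect_equal(nrow(sw), 4)
  expect_true(all(sw$LO123_scatter >= 0))
  expect_true(all(sw$LO >= sw$LO123_scatter - 1e-9))
  expect_error(sweep_sphere_sizes(radii_cm = 1), "length")
})

test_that("mouse-size sweep emits the organ-by-size table with COV", {
  sw <- sweep_mouse_sizes(sizes = tibble::tibble(radius_cm = 2,
                                                 length_cm = 6),
                          organs = c("kidney", "heart"),
                          n_decays = 2e4, n_reps = 2, seed = 6, voxel_mm = 1)
  expect_equal(nrow(sw), 2)
  expect_true(all(c("e123", "e123_sd", "e123_cov") %in% names(sw)))
  expect_true(all(lengths(sw$per_rep) == 2))
})

test_that("activity-ratio sweep emits all cells with finite errors", {
  sw <- sweep_activity_ratios(ratios = c("1:1", "2:1"),
                              conditions = c("ideal", "uncorrected",
                                             "corrected"),
                              modes = "MGP", n_decays123 = 2e4, n_reps = 2,
                              seed = 7, voxel_mm = 1)
  expect_equal(nrow(sw), 2 * 3 * 2)
  expect_true(all(is.finite(sw$r125)))
  expect_true(all(sw$abs_r125 == abs(sw$r125)))
  expect_equal(length(unique(sw$e123_cal)), 1)
})

test_that("result tables round-trip through disk exactly", {
  sw <- sweep_imaging_conditions(n_decays = 5e3, n_reps = 1, seed = 8)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_results(sw, p)
  back <- read_results(p)
  expect_equal(as.data.frame(back)[, c("LO", "HI", "e123")],
               as.data.frame(sw)[, c("LO", "HI", "e123")])
  expect_error(write_results(sw[0, ], p), "nrow")
})

test_that("plots build from sweep outputs", {
  lad <- sweep_imaging_conditions(n_decays = 5e3, n_reps = 1, seed = 9)
  expect_s3_class(plot_window_totals(lad), "ggplot")
  res <- run_scenario(small_sphere_cfg())
  expect_s3_class(autoplot(res), "ggplot")
  set.seed(10)
  e <- sample_emission_energies(iodine_spectrum("I125"), 1000)
  ev <- detect_events(tibble::tibble(energy_kev = e, n_scatters = 0,
                                     escaped = TRUE, isotope = "I125"),
                      spect_system("ideal4pi"))
  expect_s3_class(plot_spectrum(ev), "ggplot")
})
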