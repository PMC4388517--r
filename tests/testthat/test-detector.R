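escapes_tbl <- function(e, iso = "I123", ns = 0) {
  tibble::tibble(energy_kev = e, n_scatters = ns, escaped = TRUE,
                 isotope = iso)
}

test_that("energy blurring has the stated Gaussian width and identity limit", {
  expect_equal(blur_energy(c(27.5, 159), 0), c(27.5, 159))
  set.seed(31)
  x <- blur_energy(rep(159, 5e4), 0.11)
  expect_equal(sd(x), 0.11 * 159 / 2.35482, tolerance = 0.02)
  expect_equal(mean(x), 159, tolerance = 3 * sd(x) / sqrt(5e4) / 159)
})

test_that("low-window retention of a blurred 27.5 keV line matches the Gaussian CDF", {
  set.seed(32)
  n <- 2e5
  x <- blur_energy(rep(27.5, n), 0.28)
  p <- mean(x >= 25 & x < 45)
  sig <- 0.28 * 27.5 / 2.35482
  expected <- pnorm(45, 27.5, sig) - pnorm(25, 27.5, sig)
  expect_equal(p, expected, tolerance = 3 * sqrt(expected * (1 - expected) / n) / expected)
  expect_lt(p, 1)  # truncation loss drives e123 down under blurring
})

test_that("ideal mode detects every escape at weight one; planar weights follow geometry", {
  ev <- detect_events(escapes_tbl(rep(159, 10)), spect_system("ideal4pi"))
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$weight == 1))
  sys <- spect_system("MGP")
  # at 27.5 keV the tungsten shield is opaque and the crystal stops
  # everything: weight = two-head pinhole solid-angle fraction
  geo <- 2 * 1 * 0.1^2 / (16 * 2.5^2)
  expect_equal(acceptance_weight(sys, 27.5), geo, tolerance = 0.001)
  # at 159 keV shield penetration adds to the pinhole term
  expect_gt(acceptance_weight(sys, 159), acceptance_weight(sys, 27.5))
  # MWB has five pinholes at 30 mm
  geo_mwb <- 2 * 5 * 0.1^2 / (16 * 3^2)
  expect_equal(acceptance_weight(spect_system("MWB"), 27.5), geo_mwb,
               tolerance = 0.001)
  # zero-aperture system detects nothing through the pinhole pathway
  tiny <- spect_system("MGP")
  tiny$pinhole_d_cm <- 0
  expect_lt(acceptance_weight(tiny, 27.5), 1e-10)
})

test_that("detector-assembly scatter branch records partial deposits", {
  set.seed(33)
  ev <- detect_events(escapes_tbl(rep(159, 2e4)),
                      spect_system("ideal4pi", housing = TRUE))
  expect_true(any(ev$detector_scatter))
  expect_true(all(ev$recorded_kev[ev$detector_scatter] < 159))
  expect_true(all(ev$recorded_kev[!ev$detector_scatter] == 159))
  # deposits bounded by the Compton edge E - E'(pi)
  edge <- 159 - compton_energy(159, pi)
  expect_true(all(ev$recorded_kev[ev$detector_scatter] <= edge + 1e-9))
  # branch probability equals the NaI incoherent share
  p <- mu_component("sodium_iodide", 159, "incoherent") /
    mu_total("sodium_iodide", 159)
  expect_equal(mean(ev$detector_scatter), p,
               tolerance = 3 * sqrt(p * (1 - p) / 2e4) / p)
})

test_that("binning conserves weights, decomposes by isotope, and is half-open", {
  ev <- detect_events(
    dplyr::bind_rows(escapes_tbl(c(30, 160, 45), "I123"),
                     escapes_tbl(c(30, 25), "I125")),
    spect_system("ideal4pi"))
  ct <- bin_events(ev, blur = FALSE)
  tot <- window_totals(ct)
  # 45 falls in LO_upper (half-open bounds), 25 in LO
  expect_equal(tot$LO, 3)
  expect_equal(tot$LO123, 1)
  expect_equal(tot$LO125, 2)
  expect_equal(tot$HI, 1)
  expect_equal(tot$HI123, 1)
  expect_equal(tot$LO, tot$LO123 + tot$LO125)
  expect_equal(tot$HI, tot$HI123 + tot$HI125)
  expect_equal(sum(ct$counts[ct$window == "LO_upper"]), 1)
  # empty event list gives all-zero counts
  tot0 <- window_totals(bin_events(ev[0, ], blur = FALSE))
  expect_true(all(tot0 == 0))
  # overlapping windows on one head are rejected
  bad <- tibble::tibble(window = c("a", "b"), low = c(10, 15),
                        high = c(20, 25), head = "LO")
  expect_error(bin_events(ev, windows = bad), "overlap")
})

test_that("unblurred 123I events reproduce the emission window fractions", {
  set.seed(34)
  n <- 2e5
  e <- sample_emission_energies(iodine_spectrum("I123"), n)
  ev <- detect_events(escapes_tbl(e), spect_system("ideal4pi", blur = FALSE))
  tot <- window_totals(bin_events(ev, blur = FALSE))
  for (frac in list(c(tot$LO, 0.504 / 0.999), c(tot$HI, 0.484 / 0.999))) {
    sigma <- sqrt(n * frac[2] * (1 - frac[2]))
    expect_lt(abs(frac[1] - n * frac[2]), 3 * sigma)
  }
})

test_that("spectrum histogram conserves counts and peaks where expected", {
  set.seed(35)
  n <- 5e4
  e <- sample_emission_energies(iodine_spectrum("I123"), n)
  ev <- detect_events(escapes_tbl(e), spect_system("ideal4pi"))
  h0 <- spectrum_histogram(ev, bin_kev = 2, head = "none")
  expect_equal(sum(h0$counts), n)  # all lines below max_kev
  expect_equal(nrow(h0), 4)        # unblurred lines occupy single bins
  hb <- spectrum_histogram(ev, bin_kev = 2, head = "HI", max_kev = 700)
  expect_gte(sum(hb$counts), 0.999 * n)  # blur can push 528 keV over range
  hi_part <- hb[hb$energy_kev > 100 & hb$energy_kev < 300, ]
  peak <- hi_part$energy_kev[which.max(hi_part$counts)]
  expect_lt(abs(peak - 159), 6)
  low <- hb[hb$energy_kev < 45, ]
  expect_gt(sum(low$counts), 0.3 * n)  # low-energy x-ray cluster
})

test_that("blur draws are shared across windows of one head", {
  # an event on a window boundary must land in exactly one of the adjacent
  # windows, never both and never neither (within the covered range)
  set.seed(36)
  ev <- detect_events(escapes_tbl(rep(45, 500)), spect_system("ideal4pi"))
  ct <- bin_events(ev, blur = TRUE)
  lo_side <- sum(ct$counts[ct$window %in% c("LO", "LO_lower", "LO_upper")])
  e_blur_range <- ct$counts[ct$window == "LO_upper"]
  expect_lte(lo_side, 500)
  expect_gt(e_blur_range, 0)
})
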