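#' Energy windows and detector heads
#'
#' The dual-head acquisition uses a high-energy window of 148-170 keV (11%
#' FWHM energy blurring) for the 123I photopeak and a low-energy window of
#' 25-45 keV (28% blurring) for the overlapping 123I/125I x-ray region.
#' Flanking sub-windows (15-25 and 45-55 keV around LO; 127-143 and 175-191
#' keV around HI) feed the dual-energy-window scatter correction. Window
#' membership is half-open `[low, high)`, so adjacent windows partition the
#' energy axis without double counting.
#'
#' @return `default_windows()`: a tibble with columns `window`, `low`, `high`
#'   (keV) and `head` (`"HI"` or `"LO"`, which head's blurring applies).
#'   `default_heads()`: a tibble with `head` and `fwhm_frac`.
#' @export
default_windows <- function() {
  tibble::tribble(
    ~window,     ~low, ~high, ~head,
    "LO",          25,    45, "LO",
    "HI",         148,   170, "HI",
    "LO_lower",    15,    25, "LO",
    "LO_upper",    45,    55, "LO",
    "HI_lower",   127,   143, "HI",
    "HI_upper",   175,   191, "HI")
}

#' @rdname default_windows
#' @export
default_heads <- function() {
  tibble::tibble(head = c("HI", "LO"), fwhm_frac = c(0.11, 0.28))
}

#' SPECT system description
#'
#' Bundles detector geometry and physics flags. Three acceptance modes:
#' * `"ideal4pi"`: every escaping photon is detected with weight 1 and its
#'   full energy is recorded (idealized bookkeeping mode used by closed-form
#'   oracles).
#' * `"MGP"`: mouse-general-purpose-like single 1.0 mm pinhole at 25 mm
#'   radius of rotation.
#' * `"MWB"`: mouse-whole-body-like five 1.0 mm pinholes at 30 mm radius.
#'
#' In the planar (pinhole) modes each photon is detected with a weight equal
#' to its expected detection probability: the two-head pinhole solid-angle
#' fraction plus an energy-dependent shield-penetration pathway (transmission
#' through an effective tungsten shield times the detector-face solid angle),
#' both multiplied by the NaI crystal stopping probability. Weighting (rather
#' than accept/reject) keeps the full Monte Carlo statistics at desk-scale
#' decay counts; window counts are then expected counts and need not be
#' integers.
#'
#' With `housing = TRUE` the detector-assembly scatter model is active:
#' a detected photon undergoes a Compton interaction in the crystal assembly
#' with probability equal to the NaI incoherent share of the total interaction
#' cross-section at its energy, and the *recorded* energy is then the
#' Compton-electron deposit `E - E'` (Klein-Nishina angle) instead of the full
#' photon energy. This is the mechanism by which the high-energy 159 and 528
#' keV emissions contaminate the low window.
#'
#' @param mode `"ideal4pi"`, `"MGP"` or `"MWB"`.
#' @param housing Enable detector-assembly Compton scatter (partial-energy
#'   deposits). Off by default; on in the scatter-rich scenarios.
#' @param blur Apply Gaussian energy blurring at binning time.
#' @param shield_cm Effective tungsten shield thickness for the penetration
#'   pathway (planar modes), cm.
#' @param crystal_cm NaI crystal thickness, cm.
#' @param face_half_cm Detector face half-width, cm (sets the penetration
#'   solid angle).
#' @return A list of class `spect_system`.
#' @export
spect_system <- function(mode = c("ideal4pi", "MGP", "MWB"),
                         housing = FALSE, blur = TRUE,
                         shield_cm = 0.3, crystal_cm = 1.0,
                         face_half_cm = 5.0) {
  mode <- match.arg(mode)
  geom <- switch(mode,
    ideal4pi = list(n_pinholes = NA, pinhole_d_cm = NA, radius_cm = NA),
    MGP = list(n_pinholes = 1L, pinhole_d_cm = 0.1, radius_cm = 2.5),
    MWB = list(n_pinholes = 5L, pinhole_d_cm = 0.1, radius_cm = 3.0))
  structure(c(list(mode = mode, housing = housing, blur = blur,
                   shield_cm = shield_cm, crystal_cm = crystal_cm,
                   face_half_cm = face_half_cm, n_heads = 2L), geom),
            class = "spect_system")
}

#' Detection weight (expected detection probability) per photon energy
#'
#' @param system A [spect_system()].
#' @param energy_kev Photon energies, keV.
#' @return Numeric vector of weights; all 1 in `ideal4pi` mode.
#' @export
acceptance_weight <- function(system, energy_kev) {
  if (system$mode == "ideal4pi") return(rep(1, length(energy_kev)))
  geo <- system$n_heads * system$n_pinholes *
    system$pinhole_d_cm^2 / (16 * system$radius_cm^2)
  ct <- system$radius_cm /
    sqrt(system$radius_cm^2 + system$face_half_cm^2)
  face <- system$n_heads * (1 - ct) / 2
  pen <- face * exp(-mu_total("tungsten", energy_kev) * system$shield_cm)
  stop_prob <- 1 - exp(-mu_total("sodium_iodide", energy_kev) *
                         system$crystal_cm)
  (geo + pen) * stop_prob
}

#' Gaussian energy blurring
#'
#' Samples a Gaussian with mean `energy_kev` and FWHM equal to
#' `fwhm_frac * energy_kev` (sigma = FWHM / 2.3548), clipped at a 1 keV floor.
#'
#' @param energy_kev Recorded energies, keV.
#' @param fwhm_frac FWHM as a fraction of energy, in `[0, 1)`.
#' @return Blurred energies, keV.
#' @export
blur_energy <- function(energy_kev, fwhm_frac) {
  stopifnot(fwhm_frac >= 0, fwhm_frac < 1)
  if (fwhm_frac == 0) return(energy_kev)
  pmax(1, stats::rnorm(length(energy_kev), mean = energy_kev,
                       sd = fwhm_frac * energy_kev / 2.35482))
}

#' Turn escaped photons into detection events
#'
#' Assigns each escaped photon its detection weight for the system's
#' acceptance mode and, when the housing flag is set, applies the
#' detector-assembly Compton branch that replaces the recorded energy by a
#' partial Klein-Nishina deposit.
#'
#' @param escapes Tibble of escaped photons with columns `energy_kev`,
#'   `isotope`, `n_scatters` (e.g. from [transport_photons()] plus an isotope
#'   label). Rows with `escaped == FALSE`, if present, are dropped.
#' @param system A [spect_system()].
#' @return Event tibble: `recorded_kev` (pre-blur recorded energy), `weight`,
#'   `isotope`, `n_scatters`, `detector_scatter` (logical).
#' @export
detect_events <- function(escapes, system) {
  if ("escaped" %in% names(escapes)) escapes <- escapes[escapes$escaped, ]
  e <- escapes$energy_kev
  w <- acceptance_weight(system, e)
  recorded <- e
  det_sc <- rep(FALSE, length(e))
  if (isTRUE(system$housing) && length(e) > 0) {
    p_c <- mu_component("sodium_iodide", e, "incoherent") /
      pmax(mu_total("sodium_iodide", e), 1e-12)
    det_sc <- stats::runif(length(e)) < p_c
    if (any(det_sc)) {
      th <- sample_kn_angle(e[det_sc])
      recorded[det_sc] <- pmax(1, e[det_sc] - compton_energy(e[det_sc], th))
    }
  }
  tibble::tibble(recorded_kev = recorded, weight = w,
                 isotope = escapes$isotope,
                 n_scatters = escapes$n_scatters,
                 detector_scatter = det_sc)
}

#' Bin detection events into energy windows
#'
#' Applies each head's Gaussian energy blurring once per event (so all windows
#' served by one head see the same blurred energy) and accumulates event
#' weights into half-open windows, decomposed by source isotope.
#'
#' @param events Event tibble from [detect_events()].
#' @param windows Window tibble (default [default_windows()]); windows sharing
#'   a head must not overlap.
#' @param heads Head tibble (default [default_heads()]).
#' @param blur Apply blurring (`FALSE` gives the no-blur limit).
#' @return Window-count tibble: one row per `window` x `isotope` with `counts`
#'   (summed weights; integers in unweighted modes), plus the window bounds.
#' @export
bin_events <- function(events, windows = default_windows(),
                       heads = default_heads(), blur = TRUE) {
  for (h in unique(windows$head)) {
    w <- windows[windows$head == h, ]
    w <- w[order(w$low), ]
    if (nrow(w) > 1 && any(w$high[-nrow(w)] > w$low[-1]))
      stop("windows on head ", h, " overlap")
  }
  isotopes <- unique(events$isotope)
  if (length(isotopes) == 0L) isotopes <- character(0)
  blurred <- list()
  for (i in seq_len(nrow(heads))) {
    h <- heads$head[i]
    blurred[[h]] <- if (blur && nrow(events) > 0)
      blur_energy(events$recorded_kev, heads$fwhm_frac[i])
    else events$recorded_kev
  }
  out <- tidyr::expand_grid(window = windows$window,
                            isotope = if (length(isotopes)) isotopes else NA_character_)
  out <- dplyr::left_join(out, windows, by = "window")
  out$counts <- vapply(seq_len(nrow(out)), function(r) {
    if (is.na(out$isotope[r]) || nrow(events) == 0) return(0)
    be <- blurred[[out$head[r]]]
    sel <- events$isotope == out$isotope[r] &
      be >= out$low[r] & be < out$high[r]
    sum(events$weight[sel])
  }, numeric(1))
  out[, c("window", "isotope", "low", "high", "counts")]
}

#' Wide per-window totals from a window-count tibble
#'
#' @param counts Output of [bin_events()] (or a corrected version of it).
#' @return A one-row tibble with columns `LO`, `HI`, and per-isotope
#'   decompositions `LO123`, `HI123`, `LO125`, `HI125` (0 when the isotope is
#'   absent), satisfying `LO = LO123 + LO125` and `HI = HI123 + HI125`.
#' @export
window_totals <- function(counts) {
  get <- function(win, iso = NULL) {
    sel <- counts$window == win
    if (!is.null(iso)) sel <- sel & counts$isotope %in% iso
    sum(counts$counts[sel])
  }
  tibble::tibble(LO = get("LO"), HI = get("HI"),
                 LO123 = get("LO", "I123"), HI123 = get("HI", "I123"),
                 LO125 = get("LO", "I125"), HI125 = get("HI", "I125"))
}

#' Energy spectrum histogram of detection events
#'
#' Bins (blurred) recorded energies per isotope for plotting, emulating the
#' acquired energy spectra.
#'
#' @param events Event tibble from [detect_events()].
#' @param bin_kev Bin width in keV (> 0).
#' @param head Which head's blurring to apply (`"LO"`, `"HI"`, or `"none"`).
#' @param heads Head tibble (default [default_heads()]).
#' @param max_kev Upper edge of the histogram.
#' @return Tibble with `energy_kev` (bin midpoints), `isotope`, `counts`
#'   (summed weights). Total counts equal the summed event weights within
#'   range.
#' @export
spectrum_histogram <- function(events, bin_kev = 2, head = "none",
                               heads = default_heads(), max_kev = 600) {
  stopifnot(bin_kev > 0)
  e <- events$recorded_kev
  if (head != "none" && nrow(events) > 0)
    e <- blur_energy(e, heads$fwhm_frac[heads$head == head])
  breaks <- seq(0, max_kev + bin_kev, by = bin_kev)
  keep <- e < max_kev
  bin <- findInterval(e[keep], breaks)
  df <- tibble::tibble(energy_kev = breaks[bin] + bin_kev / 2,
                       isotope = events$isotope[keep],
                       weight = events$weight[keep])
  dplyr::summarise(dplyr::group_by(df, .data$energy_kev, .data$isotope),
                   counts = sum(.data$weight), .groups = "drop")
}
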