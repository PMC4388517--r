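#' Discrete line spectra of the iodine imaging isotopes
#'
#' The two radioiodines are modelled by their primary photon emission lines
#' only: for 123I the 528, 159, 31 and 27.5 keV lines (emission probabilities
#' 1.1%, 48.4%, 9.3% and 41.1% per decay) and for 125I the 35.5, 31 and
#' 27.5 keV lines (4.5%, 17.6% and 77.9%). All other emissions are omitted.
#' The high-energy 528 keV line of 123I is retained even though it lies outside
#' both acquisition windows, because it can reach the low window through
#' downscatter and detector-assembly scatter.
#'
#' A spectrum is an ordinary tibble with columns `energy_kev` and `intensity`
#' plus an `isotope` attribute, so it pipes straight into `dplyr` verbs.
#'
#' @param isotope `"I123"` or `"I125"`.
#' @param normalize Normalize intensities to sum to 1 (default `TRUE`;
#'   the printed 123I branching fractions sum to 99.9%).
#' @return A tibble with columns `energy_kev`, `intensity`, ordered by
#'   decreasing energy.
#' @examples
#' iodine_spectrum("I123")
#' @export
iodine_spectrum <- function(isotope = c("I123", "I125"), normalize = TRUE) {
  isotope <- match.arg(isotope)
  spec <- switch(isotope,
    I123 = tibble::tibble(
      energy_kev = c(528, 159, 31, 27.5),
      intensity  = c(0.011, 0.484, 0.093, 0.411)),
    I125 = tibble::tibble(
      energy_kev = c(35.5, 31, 27.5),
      intensity  = c(0.045, 0.176, 0.779)))
  attr(spec, "isotope") <- isotope
  if (normalize) normalize_spectrum(spec) else spec
}

validate_spectrum <- function(spectrum) {
  stopifnot(is.data.frame(spectrum),
            all(c("energy_kev", "intensity") %in% names(spectrum)))
  if (nrow(spectrum) == 0L) stop("spectrum has no emission lines")
  if (any(spectrum$intensity <= 0)) stop("emission intensities must be positive")
  if (any(spectrum$energy_kev <= 0)) stop("line energies must be positive")
  if (anyDuplicated(spectrum$energy_kev)) stop("line energies must be distinct")
  invisible(spectrum)
}

#' Normalize a line spectrum so intensities sum to one
#'
#' Relative line proportions are preserved; only the overall scale changes.
#'
#' @param spectrum A line-spectrum tibble (see [iodine_spectrum()]).
#' @return The spectrum with `intensity` summing to exactly 1.
#' @export
normalize_spectrum <- function(spectrum) {
  validate_spectrum(spectrum)
  spectrum$intensity <- spectrum$intensity / sum(spectrum$intensity)
  spectrum
}

is_normalized <- function(spectrum, tol = 1e-8) {
  abs(sum(spectrum$intensity) - 1) < tol
}

#' Sample photon emission energies from a line spectrum
#'
#' Draws `n` photon energies with per-line probabilities equal to the line
#' intensities. Uses R's global random stream, so results are reproducible
#' under [set.seed()].
#'
#' @param spectrum A normalized line-spectrum tibble.
#' @param n Number of photons to draw (`n >= 0`).
#' @return Numeric vector of `n` energies in keV, each equal to a line energy.
#' @export
sample_emission_energies <- function(spectrum, n) {
  validate_spectrum(spectrum)
  if (!is_normalized(spectrum))
    stop("spectrum must be normalized (see normalize_spectrum())")
  stopifnot(length(n) == 1L, n >= 0)
  if (n == 0) return(numeric(0))
  spectrum$energy_kev[sample.int(nrow(spectrum), n, replace = TRUE,
                                 prob = spectrum$intensity)]
}

#' Emission fraction falling inside an energy window
#'
#' Closed-form (no-blur, no-medium) fraction of emitted photons whose line
#' energy lies in the half-open window `[low, high)`. Adjacent windows
#' therefore partition the energy axis without double counting.
#'
#' @param spectrum A normalized line-spectrum tibble.
#' @param low,high Window bounds in keV, `low <= high`.
#' @return Scalar fraction in `[0, 1]`.
#' @examples
#' line_fraction_in_window(iodine_spectrum("I123"), 25, 45)   # 0.504...
#' line_fraction_in_window(iodine_spectrum("I123"), 148, 170) # 0.484...
#' @export
line_fraction_in_window <- function(spectrum, low, high) {
  validate_spectrum(spectrum)
  if (!is_normalized(spectrum))
    stop("spectrum must be normalized (see normalize_spectrum())")
  if (high < low) stop("inverted window bounds: high < low")
  sum(spectrum$intensity[spectrum$energy_kev >= low &
                           spectrum$energy_kev < high])
}
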