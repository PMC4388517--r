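Package: dualspect
Title: Dual-Isotope SPECT Spectrum Overlap Simulation and Stripping Correction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale Monte Carlo study of spectrum overlap between 123I and
    125I in preclinical dual-isotope SPECT. Provides discrete iodine line
    spectra, synthetic sphere and mouse-like voxel phantoms, a simplified
    photon transport kernel (Woodcock delta tracking with photoelectric
    absorption and Klein-Nishina Compton scattering), a pinhole detector model
    with Gaussian energy blurring and detector-assembly scatter, the
    ratio-based spectrum-stripping correction (e123 calibration, low-window
    stripping, relative estimation error r125), dual-energy-window scatter and
    analytic attenuation corrections, and scenario sweeps over phantom sizes
    and isotope activity ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    ggplot2,
    rlang,
    generics,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
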