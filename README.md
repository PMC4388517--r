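# dualspect

Desk-scale Monte Carlo study of spectrum overlap between ¹²³I and ¹²⁵I in
preclinical dual-isotope SPECT, and of the ratio-based spectrum-stripping
correction that separates the two tracers.

## The problem

Labelling two biological radiotracers with two radioiodines (¹²³I and ¹²⁵I)
allows a head-to-head comparison in a single animal with identical
radiochemistry. The ¹²³I photopeak at 159 keV is acquired cleanly in a
high-energy window (HI, 148–170 keV), but the low-energy window
(LO, 25–45 keV) receives an *identical* x-ray/γ cluster (27.5, 31, 35.5 keV)
from both isotopes, plus downscattered high-energy photons. The standard fix
is spectrum stripping:

- calibrate the overlap ratio from pure-¹²³I data,
  `e123 = LO123 / HI123`;
- strip the ¹²³I contamination from a mixed acquisition,
  `Estimate125 = LO − e123 × HI`;
- in simulation, score the relative estimation error
  `r125 = (Actual125 − Estimate125) / Actual125`, since every simulated
  photon carries its true isotope label.

`dualspect` provides the whole chain as composable, pipe-friendly functions:
discrete iodine line spectra; synthetic sphere and mouse-like voxel phantoms;
a simplified photon-transport kernel (Woodcock delta tracking, photoelectric
absorption, Klein–Nishina Compton scattering, in C++); a dual-head pinhole
detector model with Gaussian energy blurring, shield penetration and
detector-assembly scatter; dual-energy-window (DEW) scatter and analytic
attenuation corrections; and scenario sweeps over imaging conditions,
phantom sizes and activity ratios, with `tidy()`/`glance()`/`autoplot()`
methods on results.

## Worked example

```r
library(dualspect)

lad <- sweep_imaging_conditions(n_decays = 1e5, n_reps = 3, seed = 1)
dplyr::summarise(dplyr::group_by(lad, condition),
                 e123 = mean(e123), LO = mean(LO), HI = mean(HI))
#> # A tibble: 3 × 4
#>   condition  e123    LO    HI
#>   <fct>     <dbl> <dbl> <dbl>
#> 1 ideal     0.451 10.1   22.4
#> 2 blur      0.425  8.18  19.3
#> 3 scatter   0.764 13.3   17.4
```

Reading the table: under ideal conditions the low-to-high ratio of the
pinhole system is ~0.45. Switching on detector energy blurring lowers it
(the 28% FWHM blurring of the low window truncates more counts than the 11%
blurring of the high window). Adding a water medium and detector-assembly
scatter raises the low-window total (high-energy photons recorded at partial
Compton-deposit energies) while the high window loses counts — so the ratio
rises sharply, and any stripping calibrated under different conditions will
misestimate. Counts are expected (acceptance-weighted) counts per 1e5 decays.

The stripping validation itself:

```r
sw <- sweep_activity_ratios(modes = "MGP", n_decays123 = 1e6, n_reps = 5, seed = 1)
plot_stripping_error(sw)   # |r125| per ratio, faceted by condition
```

`|r125|` is smallest at the 1:2 ratio (more ¹²⁵I, relatively less overlap),
largest at 2:1, grows sharply when attenuation and scatter are left
uncorrected, and drops back once DEW + attenuation corrections are applied to
the same acquired data.

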