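#' Compton-scattered photon energy
#'
#' Closed-form Compton kinematics: `E' = E / (1 + (E/511)(1 - cos(theta)))`.
#' Vectorized over both arguments.
#'
#' @param energy_kev Incident photon energy, keV (> 0).
#' @param angle Scattering angle in radians, in `[0, pi]`.
#' @return Scattered photon energy in keV (`<= energy_kev`).
#' @examples
#' compton_energy(159, pi)  # backscatter, ~98 keV
#' @export
compton_energy <- function(energy_kev, angle) {
  stopifnot(all(energy_kev > 0), all(angle >= 0), all(angle <= pi + 1e-12))
  energy_kev / (1 + (energy_kev / 511) * (1 - cos(angle)))
}

#' Sample Klein-Nishina scattering angles
#'
#' Draws Compton scattering angles from the Klein-Nishina differential
#' cross-section at the given energy (Kahn's rejection method). Uses R's
#' global random stream.
#'
#' @param energy_kev Photon energy in keV; scalar or vector of length `n`.
#' @param n Number of angles to draw.
#' @return Numeric vector of scattering angles in radians, in `[0, pi]`.
#' @export
sample_kn_angle <- function(energy_kev, n = length(energy_kev)) {
  stopifnot(all(energy_kev > 0))
  e <- rep_len(energy_kev, n)
  acos(pmin(1, pmax(-1, cpp_kn_cos_angles(e))))
}

transport_lookup <- function(phantom) {
  lk <- attenuation_lookup()
  present <- sort(unique(as.integer(phantom$material)))
  keep <- matrix(0, nrow = nrow(lk$mu_pe), ncol = ncol(lk$mu_pe))
  keep[, present + 1L] <- 1
  list(mu_pe = lk$mu_pe * keep, mu_inc = lk$mu_inc * keep,
       emin = lk$energies[1], estep = E_STEP)
}

#' Transport photons through a voxel phantom
#'
#' Simplified Monte Carlo photon transport: isotropic emission, Woodcock
#' (delta-tracking) free-path sampling against the grid majorant attenuation,
#' photoelectric absorption, and Klein-Nishina Compton scattering. Histories
#' terminate on escape from the grid, photoelectric absorption, falling below
#' the energy cutoff, or exceeding `max_scatters` (counted as absorbed).
#'
#' @param phantom A [voxel_phantom].
#' @param positions `n x 3` matrix of emission positions (world cm), inside
#'   the grid.
#' @param energies Length-`n` vector of emission energies, keV.
#' @param max_scatters Maximum Compton scatters per history; `0` makes every
#'   interaction terminal (absorption-only mode, Beer-Lambert escape).
#' @param e_cutoff Energy cutoff in keV; photons below it count as absorbed.
#' @return A tibble with one row per photon: `energy_kev` (current energy;
#'   exit energy when escaped), `n_scatters`, and logical `escaped`.
#'   Escaped + absorbed = emitted, exactly.
#' @export
transport_photons <- function(phantom, positions, energies,
                              max_scatters = 20L, e_cutoff = 10) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(energies))
  d <- dim(phantom$material)
  upper <- phantom$origin + d * phantom$voxel_cm
  inside <- positions[, 1] >= phantom$origin[1] & positions[, 1] < upper[1] &
            positions[, 2] >= phantom$origin[2] & positions[, 2] < upper[2] &
            positions[, 3] >= phantom$origin[3] & positions[, 3] < upper[3]
  if (!all(inside)) stop("emission positions must lie inside the phantom grid")
  lk <- transport_lookup(phantom)
  res <- cpp_transport(positions, energies,
                       as.integer(phantom$material), as.integer(d),
                       phantom$origin, phantom$voxel_cm,
                       lk$mu_pe, lk$mu_inc, lk$emin, lk$estep,
                       as.integer(max_scatters), e_cutoff)
  tibble::tibble(energy_kev = res$energy_kev,
                 n_scatters = res$n_scatters,
                 escaped = res$escaped == 1L)
}

#' Mean transmission from source voxels toward a direction
#'
#' Ray-marches from each point to the grid boundary along `direction` and
#' returns `exp(-integral of mu dl)` per point, at a single representative
#' photon energy. Used by the analytic attenuation correction.
#'
#' @param phantom A [voxel_phantom].
#' @param points `m x 3` matrix of world coordinates (cm).
#' @param direction Length-3 direction vector (normalized internally).
#' @param energy_kev Representative photon energy for the attenuation lookup.
#' @return Numeric vector of transmissions in `(0, 1]`.
#' @export
ray_transmission <- function(phantom, points, direction, energy_kev) {
  points <- as.matrix(points)
  direction <- direction / sqrt(sum(direction^2))
  mu_by_mat <- vapply(names(MATERIALS), function(m) {
    if (m == "vacuum") 0 else mu_total(m, energy_kev)
  }, numeric(1))
  cpp_ray_transmission(points, direction,
                       as.integer(phantom$material),
                       as.integer(dim(phantom$material)),
                       phantom$origin, phantom$voxel_cm,
                       unname(mu_by_mat))
}
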