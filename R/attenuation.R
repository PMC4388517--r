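#' Photon attenuation data
#'
#' The package ships a compact analytic attenuation table
#' (`inst/extdata/attenuation.tsv`) covering 10-600 keV for the materials used
#' by the simulator. Mass coefficients are split into a photoelectric and an
#' incoherent (Compton) component; the incoherent part is the closed-form
#' Klein-Nishina cross-section (free-electron approximation) and the
#' photoelectric part is a piecewise log-log power law anchored at standard
#' reference coefficients, with K-edge jumps for iodine and tungsten.
#' Coherent (Rayleigh) scattering is excluded, consistent with the transport
#' physics, so `total = photoelectric + incoherent` at every grid point.
#'
#' @name attenuation
NULL

MATERIALS <- c(vacuum = 0L, water = 1L, soft_tissue = 2L, lung = 3L,
               bone = 4L, aluminum = 5L, sodium_iodide = 6L, tungsten = 7L)

DENSITY <- c(vacuum = 0, water = 1.0, soft_tissue = 1.06, lung = 0.26,
             bone = 1.92, aluminum = 2.699, sodium_iodide = 3.667,
             tungsten = 19.30)

E_MIN <- 10
E_MAX <- 600
E_STEP <- 0.5

#' Material reference table
#'
#' @return A tibble with one row per material: `material`, integer `id` used in
#'   voxel grids, and `density` in g/cm^3.
#' @export
material_table <- function() {
  tibble::tibble(material = names(MATERIALS),
                 id = unname(MATERIALS),
                 density = unname(DENSITY[names(MATERIALS)]))
}

#' Read the shipped attenuation table
#'
#' @return A tibble with columns `material`, `energy_kev`,
#'   `mu_rho_photoelectric`, `mu_rho_incoherent` (cm^2/g).
#' @export
attenuation_table <- function() {
  path <- system.file("extdata", "attenuation.tsv", package = "dualspect",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

# Fine linear-energy lookup grids (log-log interpolated from the shipped
# table), cached per session. Rows = energies E_MIN..E_MAX by E_STEP,
# columns = material ids 0..7. Values are *linear* coefficients (1/cm).
attenuation_lookup <- function() {
  if (!is.null(the$mu_lookup)) return(the$mu_lookup)
  tab <- attenuation_table()
  energies <- seq(E_MIN, E_MAX, by = E_STEP)
  nmat <- length(MATERIALS)
  mu_pe <- matrix(0, nrow = length(energies), ncol = nmat)
  mu_inc <- matrix(0, nrow = length(energies), ncol = nmat)
  for (m in names(MATERIALS)) {
    id <- MATERIALS[[m]]
    if (m == "vacuum") next
    sub <- tab[tab$material == m, ]
    sub <- sub[order(sub$energy_kev), ]
    loglog <- function(y) {
      exp(stats::approx(log(sub$energy_kev), log(pmax(y, 1e-300)),
                        xout = log(energies), rule = 2)$y)
    }
    mu_pe[, id + 1L] <- loglog(sub$mu_rho_photoelectric) * DENSITY[[m]]
    mu_inc[, id + 1L] <- loglog(sub$mu_rho_incoherent) * DENSITY[[m]]
  }
  the$mu_lookup <- list(energies = energies, mu_pe = mu_pe, mu_inc = mu_inc)
  the$mu_lookup
}

mu_interp <- function(mat_ids, energy_kev, matx) {
  lk <- attenuation_lookup()
  e <- pmin(pmax(energy_kev, E_MIN), E_MAX)
  i <- pmin(floor((e - E_MIN) / E_STEP) + 1, length(lk$energies) - 1L)
  f <- (e - lk$energies[i]) / E_STEP
  lo <- matx[cbind(i, mat_ids + 1L)]
  hi <- matx[cbind(i + 1L, mat_ids + 1L)]
  lo * (1 - f) + hi * f
}

#' Linear attenuation coefficients
#'
#' Interpolates the shipped attenuation table (log-log between tabulated
#' points) and multiplies by material density. `mu_total()` is the sum of the
#' photoelectric and incoherent components. Both functions are vectorized over
#' `energy_kev`.
#'
#' @param material Material name (see [material_table()]).
#' @param energy_kev Photon energy (or energies) in keV, within 10-600.
#' @param component `"photoelectric"` or `"incoherent"`.
#' @return Linear attenuation coefficient(s) in 1/cm; 0 for vacuum.
#' @examples
#' mu_total("water", 159)
#' @export
mu_total <- function(material, energy_kev) {
  mu_component(material, energy_kev, "photoelectric") +
    mu_component(material, energy_kev, "incoherent")
}

#' @rdname mu_total
#' @export
mu_component <- function(material, energy_kev,
                         component = c("photoelectric", "incoherent")) {
  component <- match.arg(component)
  if (!material %in% names(MATERIALS)) stop("unknown material: ", material)
  if (any(energy_kev < E_MIN | energy_kev > E_MAX))
    stop("energy out of table range [", E_MIN, ", ", E_MAX, "] keV")
  id <- MATERIALS[[material]]
  if (material == "vacuum") return(rep(0, length(energy_kev)))
  lk <- attenuation_lookup()
  matx <- if (component == "photoelectric") lk$mu_pe else lk$mu_inc
  mu_interp(rep(id, length(energy_kev)), energy_kev, matx)
}

#' Write the attenuation table to a columnar text file
#'
#' Convenience export of [attenuation_table()] for interoperability.
#'
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_attenuation_table <- function(path) {
  readr::write_tsv(attenuation_table(), path)
  invisible(path)
}
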