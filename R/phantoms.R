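#' Synthetic voxel phantoms
#'
#' Stand-ins for the digital mouse (MOBY-style) and uniform-sphere phantoms:
#' a 3-D material-ID grid plus per-isotope activity grids on the same lattice.
#' Mouse organs are parametric ellipsoids inside a soft-tissue cylinder --
#' realistic organ meshes are deliberately replaced by shapes whose analytic
#' volumes make the voxelization testable; only organ depth and bulk
#' attenuation matter for the spectrum-overlap question.
#'
#' A `voxel_phantom` is a list with elements `material` (integer 3-D array of
#' material IDs, see [material_table()]), `region` (integer 3-D array of organ
#' region codes, 0 = none), `regions` (tibble mapping organ names to codes),
#' `activity` (named list of 3-D arrays, uCi per voxel, one per isotope),
#' `voxel_cm`, and `origin` (world coordinate of the grid corner, cm; the
#' phantom axis is the scanner axis of rotation, z).
#'
#' @name voxel_phantom
NULL

new_phantom <- function(material, region, regions, activity, voxel_cm, origin) {
  structure(list(material = material, region = region, regions = regions,
                 activity = activity, voxel_cm = voxel_cm, origin = origin),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$material)
  cat("<voxel_phantom> ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_cm * 10, " mm\n", sep = "")
  cat("  regions: ", paste(x$regions$organ, collapse = ", "), "\n", sep = "")
  for (iso in names(x$activity))
    cat("  ", iso, ": ", signif(sum(x$activity[[iso]]), 6), " uCi\n", sep = "")
  invisible(x)
}

grid_coords <- function(n, voxel_cm, origin) {
  origin + (seq_len(n) - 0.5) * voxel_cm
}

#' Build a uniform sphere phantom
#'
#' A ball of `material` of radius `radius_cm`, centred in a vacuum grid, with
#' activity distributed uniformly over an inner source ball of radius
#' `source_radius_cm` (by default the whole sphere). Setting
#' `material = "vacuum"` gives the no-medium (ideal) geometry while keeping the
#' same source distribution.
#'
#' @param radius_cm Sphere radius in cm (> 0).
#' @param activities Named numeric vector of total activities in uCi, names
#'   are isotope labels (e.g. `c(I123 = 200)`).
#' @param material Sphere material (default `"water"`).
#' @param source_radius_cm Radius of the active core, cm.
#' @param voxel_mm Voxel size in mm; at least 8 voxels must span the source
#'   diameter.
#' @return A [voxel_phantom].
#' @examples
#' ph <- sphere_phantom(0.5, activities = c(I123 = 200), voxel_mm = 0.5)
#' sum(ph$activity$I123)
#' @export
sphere_phantom <- function(radius_cm, activities = c(I123 = 200),
                           material = "water",
                           source_radius_cm = min(radius_cm, 0.391),
                           voxel_mm = 0.5) {
  stopifnot(radius_cm > 0, source_radius_cm > 0,
            source_radius_cm <= radius_cm)
  voxel_cm <- voxel_mm / 10
  if (2 * radius_cm / voxel_cm < 8)
    stop("voxel size too coarse: fewer than 8 voxels span the sphere diameter")
  if (source_radius_cm < voxel_cm)
    stop("source radius smaller than a voxel")
  half <- radius_cm + 2 * voxel_cm
  n <- 2L * ceiling(half / voxel_cm)
  origin <- -n / 2 * voxel_cm
  cc <- grid_coords(n, voxel_cm, origin)
  r2 <- outer(outer(cc^2, cc^2, `+`), cc^2, `+`)  # squared distance to centre
  mat <- array(MATERIALS[["vacuum"]], dim = c(n, n, n))
  mat[r2 <= radius_cm^2] <- MATERIALS[[material]]
  region <- array(0L, dim = dim(mat))
  region[r2 <= source_radius_cm^2] <- 1L
  regions <- tibble::tibble(organ = "source", code = 1L)
  activity <- uniform_activity(region, 1L, activities)
  new_phantom(mat, region, regions, activity, voxel_cm, rep(origin, 3))
}

uniform_activity <- function(region, code, activities) {
  idx <- region %in% code
  nvox <- sum(idx)
  lapply(as.list(activities), function(a) {
    g <- array(0, dim = dim(region))
    g[idx] <- a / nvox
    g
  })
}

#' Default mouse organ layout
#'
#' Ellipsoid organ stand-ins as fractions of body radius (`cx`, `cy`, `ax`,
#' `ay`) and body length (`cz`, `az`; z measured from the caudal end): heart
#' upper-thorax midline, lungs flanking the heart, liver below the lungs,
#' spleen left-lateral, kidneys paired dorsal at mid-abdomen. Paired organs
#' are two lobes sharing one region name. Pass a modified copy to
#' [mouse_phantom()] to override.
#'
#' @return A tibble with one row per organ lobe.
#' @export
mouse_organ_layout <- function() {
  tibble::tribble(
    ~organ,   ~lobe, ~cx, ~cy, ~cz, ~ax, ~ay, ~az, ~material,
    "heart",  1L,  0.00,  0.12, 0.72, 0.16, 0.16, 0.050, "soft_tissue",
    "lung",   1L,  0.46,  0.00, 0.72, 0.25, 0.33, 0.090, "lung",
    "lung",   2L, -0.46,  0.00, 0.72, 0.25, 0.33, 0.090, "lung",
    "liver",  1L,  0.08,  0.08, 0.55, 0.55, 0.50, 0.065, "soft_tissue",
    "spleen", 1L, -0.60, -0.32, 0.50, 0.15, 0.10, 0.060, "soft_tissue",
    "kidney", 1L,  0.35, -0.45, 0.38, 0.16, 0.14, 0.055, "soft_tissue",
    "kidney", 2L, -0.35, -0.45, 0.38, 0.16, 0.14, 0.055, "soft_tissue")
}

#' Build a mouse-like voxel phantom
#'
#' A soft-tissue cylinder (radius `body_radius_cm`, length `body_length_cm`,
#' axis along z) containing ellipsoidal spleen, liver, heart, kidney and lung
#' compartments. Organ centres and semi-axes are fractions of the body
#' dimensions (see `layout`), so phantoms of different sizes are geometrically
#' similar. Activity is uniform within each named organ.
#'
#' @param body_radius_cm,body_length_cm Body cylinder dimensions, cm.
#' @param organ_activities Named list: for each organ, a named numeric vector
#'   of total activities in uCi per isotope, e.g.
#'   `list(kidney = c(I123 = 1, I125 = 1))`.
#' @param voxel_mm Voxel size in mm.
#' @param layout Organ layout tibble (defaults to [mouse_organ_layout()]);
#'   user-overridable.
#' @return A [voxel_phantom]. Errors if an organ escapes the body cylinder or
#'   two organs overlap.
#' @examples
#' ph <- mouse_phantom(2, 6, list(kidney = c(I123 = 1)), voxel_mm = 1)
#' @export
mouse_phantom <- function(body_radius_cm, body_length_cm,
                          organ_activities = list(kidney = c(I123 = 1, I125 = 1)),
                          voxel_mm = 0.5, layout = mouse_organ_layout()) {
  stopifnot(body_radius_cm > 0, body_length_cm > 0)
  voxel_cm <- voxel_mm / 10
  R <- body_radius_cm; L <- body_length_cm
  nx <- 2L * ceiling((R + 2 * voxel_cm) / voxel_cm)
  nz <- ceiling((L + 4 * voxel_cm) / voxel_cm)
  ox <- -nx / 2 * voxel_cm
  oz <- -2 * voxel_cm
  xs <- grid_coords(nx, voxel_cm, ox)
  zs <- grid_coords(nz, voxel_cm, oz)

  mat <- array(MATERIALS[["vacuum"]], dim = c(nx, nx, nz))
  body2 <- outer(xs^2, xs^2, `+`)
  body <- array(FALSE, dim = dim(mat))
  inz <- zs >= 0 & zs <= L
  for (k in which(inz)) body[, , k] <- body2 <= R^2
  mat[body] <- MATERIALS[["soft_tissue"]]

  region <- array(0L, dim = dim(mat))
  organs <- unique(layout$organ)
  regions <- tibble::tibble(organ = organs, code = seq_along(organs))
  for (i in seq_len(nrow(layout))) {
    lo <- layout[i, ]
    code <- regions$code[regions$organ == lo$organ]
    u <- (xs - lo$cx * R) / (lo$ax * R)
    v <- (xs - lo$cy * R) / (lo$ay * R)
    w <- (zs - lo$cz * L) / (lo$az * L)
    inside <- outer(outer(u^2, v^2, `+`), w^2, `+`) <= 1
    if (any(inside & !body))
      stop("organ '", lo$organ, "' escapes the body cylinder")
    if (any(region[inside] != 0L & region[inside] != code))
      stop("organ '", lo$organ, "' overlaps another organ")
    region[inside] <- code
    mat[inside] <- MATERIALS[[lo$material]]
  }

  unknown <- setdiff(names(organ_activities), organs)
  if (length(unknown)) stop("unknown organ(s): ", paste(unknown, collapse = ", "))
  isotopes <- unique(unlist(lapply(organ_activities, names)))
  activity <- setNames(lapply(isotopes, function(i) array(0, dim = dim(mat))),
                       isotopes)
  for (organ in names(organ_activities)) {
    code <- regions$code[regions$organ == organ]
    idx <- region == code
    nvox <- sum(idx)
    if (nvox == 0L) stop("organ '", organ, "' voxelized to zero volume")
    for (iso in names(organ_activities[[organ]])) {
      g <- activity[[iso]]
      g[idx] <- g[idx] + organ_activities[[organ]][[iso]] / nvox
      activity[[iso]] <- g
    }
  }
  new_phantom(mat, region, regions, activity, voxel_cm, c(ox, ox, oz))
}

#' Organ voxel mask
#'
#' @param phantom A [voxel_phantom].
#' @param organ Organ name present in the phantom's region table.
#' @return Logical 3-D array; masks of distinct organs are disjoint.
#' @export
organ_mask <- function(phantom, organ) {
  if (!organ %in% phantom$regions$organ)
    stop("unknown organ: ", organ)
  code <- phantom$regions$code[phantom$regions$organ == organ]
  phantom$region == code
}

#' Sample photon emission positions from a phantom's activity map
#'
#' Voxels are drawn with probability proportional to activity and positions
#' are jittered uniformly within the voxel.
#'
#' @param phantom A [voxel_phantom].
#' @param isotope Isotope label with an activity grid in the phantom.
#' @param n Number of positions.
#' @return An `n x 3` matrix of world coordinates (cm).
#' @export
phantom_source_positions <- function(phantom, isotope, n) {
  act <- phantom$activity[[isotope]]
  if (is.null(act)) stop("no activity grid for isotope ", isotope)
  nz <- which(act > 0)
  if (length(nz) == 0L) stop("phantom has zero ", isotope, " activity")
  pick <- nz[sample.int(length(nz), n, replace = TRUE,
                        prob = act[nz])]
  d <- dim(act)
  i <- (pick - 1L) %% d[1]
  j <- ((pick - 1L) %/% d[1]) %% d[2]
  k <- (pick - 1L) %/% (d[1] * d[2])
  jit <- matrix(stats::runif(3 * n), ncol = 3)
  cbind(phantom$origin[1] + (i + jit[, 1]) * phantom$voxel_cm,
        phantom$origin[2] + (j + jit[, 2]) * phantom$voxel_cm,
        phantom$origin[3] + (k + jit[, 3]) * phantom$voxel_cm)
}

#' Export a phantom's grids as raw binary arrays with a text sidecar
#'
#' Writes `material.bin` (int32), `region.bin` (int32) and one
#' `activity_<isotope>.bin` (float64) per isotope, column-major, plus a
#' `header.dcf` sidecar describing shape, dtype, voxel size and origin, for
#' interoperability with external voxel tools.
#'
#' @param phantom A [voxel_phantom].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_raw <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeBin(as.integer(phantom$material), file.path(dir, "material.bin"), size = 4L)
  writeBin(as.integer(phantom$region), file.path(dir, "region.bin"), size = 4L)
  for (iso in names(phantom$activity))
    writeBin(as.numeric(phantom$activity[[iso]]),
             file.path(dir, paste0("activity_", iso, ".bin")))
  hdr <- data.frame(shape = paste(dim(phantom$material), collapse = "x"),
                    material_dtype = "int32", activity_dtype = "float64",
                    order = "column-major", voxel_cm = phantom$voxel_cm,
                    origin = paste(signif(phantom$origin, 8), collapse = ","))
  write.dcf(hdr, file.path(dir, "header.dcf"))
  invisible(dir)
}
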