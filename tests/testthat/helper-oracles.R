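# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# Klein-Nishina pdf over cos(theta) (unnormalized), written from the
# differential cross-section directly.
kn_pdf_cos_oracle <- function(energy_kev, cth) {
  a <- energy_kev / 511
  r <- 1 / (1 + a * (1 - cth))
  r^2 * (r + 1 / r - (1 - cth^2))
}

# Numerically integrated CDF of the scattering angle theta in [0, pi].
kn_angle_cdf_oracle <- function(energy_kev, n_grid = 4001) {
  th <- seq(0, pi, length.out = n_grid)
  pdf_th <- kn_pdf_cos_oracle(energy_kev, cos(th)) * sin(th)
  cdf <- cumsum(pdf_th)
  cdf <- (cdf - cdf[1]) / (cdf[n_grid] - cdf[1])
  function(q) stats::approx(th, cdf, xout = q, rule = 2)$y
}

# Expected escape fraction for first-flight (absorption-only) transport from
# fixed points: average over sampled directions of exp(-optical depth), with
# the optical depth accumulated by fine ray marching through the voxel grid
# in plain R.
escape_fraction_oracle <- function(phantom, origin_pt, energy_kev,
                                   n_dirs = 2000) {
  d <- dim(phantom$material)
  vox <- phantom$voxel_cm
  mu_by_mat <- vapply(material_table()$material, function(m)
    if (m == "vacuum") 0 else mu_total(m, energy_kev), numeric(1))
  ct <- stats::runif(n_dirs, -1, 1)
  ph <- stats::runif(n_dirs, 0, 2 * pi)
  st <- sqrt(1 - ct^2)
  dirs <- cbind(st * cos(ph), st * sin(ph), ct)
  step <- vox / 5
  esc <- numeric(n_dirs)
  upper <- phantom$origin + d * vox
  for (i in seq_len(n_dirs)) {
    pos <- origin_pt
    depth <- 0
    repeat {
      pos <- pos + step * dirs[i, ]
      if (any(pos < phantom$origin) || any(pos >= upper)) break
      ijk <- pmin(pmax(floor((pos - phantom$origin) / vox) + 1, 1), d)
      mat <- phantom$material[ijk[1], ijk[2], ijk[3]]
      depth <- depth + mu_by_mat[mat + 1] * step
    }
    esc[i] <- exp(-depth)
  }
  mean(esc)
}

# Three-material toy grid: water slab, bone insert, lung shell, in vacuum.
toy_grid_phantom <- function() {
  ph <- sphere_phantom(0.8, activities = c(I123 = 1), material = "water",
                       source_radius_cm = 0.3, voxel_mm = 1)
  d <- dim(ph$material)
  mid <- round(d / 2)
  ph$material[(mid[1] - 2):(mid[1] + 2),
              (mid[2] - 2):(mid[2] + 2),
              (mid[3] - 2):(mid[3] + 2)] <- dualspect::material_table()$id[
                dualspect::material_table()$material == "bone"]
  ph$material[1:3, , ] <- dualspect::material_table()$id[
    dualspect::material_table()$material == "lung"]
  ph
}
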