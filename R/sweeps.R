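#' Imaging-condition ladder for the overlap ratio
#'
#' Runs the pure-123I source sphere through the three canonical imaging
#' conditions: (1) ideal (no blurring, no medium), (2) energy blurring only,
#' and (3) blurring plus attenuation/scatter in a water sphere with the
#' detector-assembly scatter model active. Reports per-rep low/high window
#' totals and the overlap ratio e123.
#'
#' @param n_decays 123I decays per repetition.
#' @param n_reps Repetitions per condition.
#' @param seed Master seed.
#' @param mode Detector acceptance mode (default `"MGP"`).
#' @param medium_radius_cm Water sphere radius for the scatter condition, cm.
#' @param source_radius_cm Active core radius, cm.
#' @param voxel_mm Voxel size, mm.
#' @return Tibble with one row per condition x rep: `condition`, `rep`,
#'   `LO123`, `HI123`, `LO`, `HI`, `e123`.
#' @export
sweep_imaging_conditions <- function(n_decays = 1e6, n_reps = 5, seed = 1,
                                     mode = "MGP", medium_radius_cm = 0.5,
                                     source_radius_cm = 0.391,
                                     voxel_mm = 0.5) {
  vac <- sphere_phantom(medium_radius_cm, activities = c(I123 = 200),
                        material = "vacuum",
                        source_radius_cm = source_radius_cm,
                        voxel_mm = voxel_mm)
  wat <- sphere_phantom(medium_radius_cm, activities = c(I123 = 200),
                        material = "water",
                        source_radius_cm = source_radius_cm,
                        voxel_mm = voxel_mm)
  cells <- list(
    ideal   = list(ph = vac, sys = spect_system(mode, housing = FALSE, blur = FALSE)),
    blur    = list(ph = vac, sys = spect_system(mode, housing = FALSE, blur = TRUE)),
    scatter = list(ph = wat, sys = spect_system(mode, housing = TRUE,  blur = TRUE)))
  purrr::imap(cells, function(cell, cond) {
    cfg <- scenario_config(cell$ph, cell$sys, n_decays = c(I123 = n_decays),
                           n_reps = n_reps,
                           seed = seed + match(cond, names(cells)) - 1L)
    td <- tidy(run_scenario(cfg))
    tibble::tibble(condition = cond, rep = td$rep, LO123 = td$LO123,
                   HI123 = td$HI123, LO = td$LO, HI = td$HI,
                   e123 = td$LO123 / td$HI123)
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = c("ideal", "blur", "scatter")))
}

#' Sphere-size sweep of the scatter contribution
#'
#' Runs the pure-123I source inside water spheres of increasing radius with
#' blurring and detector-assembly scatter on, tracking window totals, e123,
#' and the scattered-photon contribution to the low window.
#'
#' @param radii_cm Water sphere radii, cm (at least two).
#' @inheritParams sweep_imaging_conditions
#' @return Tibble with one row per radius x rep: window totals, `e123`, and
#'   `LO123_scatter` (low-window 123I counts from photons that scattered in
#'   the phantom or the detector assembly).
#' @export
sweep_sphere_sizes <- function(radii_cm = seq(0.5, 3, by = 0.5),
                               n_decays = 1e6, n_reps = 5, seed = 1,
                               mode = "MGP", source_radius_cm = 0.391,
                               voxel_mm = 0.5) {
  stopifnot(length(radii_cm) >= 2)
  sys <- spect_system(mode, housing = TRUE, blur = TRUE)
  purrr::map(seq_along(radii_cm), function(i) {
    r <- radii_cm[i]
    ph <- sphere_phantom(r, activities = c(I123 = 200), material = "water",
                         source_radius_cm = source_radius_cm,
                         voxel_mm = voxel_mm)
    cfg <- scenario_config(ph, sys, n_decays = c(I123 = n_decays),
                           n_reps = n_reps, seed = seed + i - 1L)
    set.seed(cfg$seed)
    purrr::map(seq_len(n_reps), function(rep) {
      ev <- simulate_rep(cfg)
      tot <- window_totals(bin_events(ev, blur = TRUE))
      sc <- ev[ev$n_scatters > 0 | ev$detector_scatter, ]
      tot_sc <- window_totals(bin_events(sc, blur = TRUE))
      tibble::tibble(radius_cm = r, rep = rep,
                     LO123 = tot$LO123, HI123 = tot$HI123,
                     LO = tot$LO, HI = tot$HI,
                     e123 = tot$LO123 / tot$HI123,
                     LO123_scatter = tot_sc$LO123)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

set_organ_activity <- function(phantom, organ, activities) {
  idx <- organ_mask(phantom, organ)
  nvox <- sum(idx)
  phantom$activity <- lapply(as.list(activities), function(a) {
    g <- array(0, dim = dim(phantom$material))
    g[idx] <- a / nvox
    g
  })
  phantom
}

#' Organ overlap ratios across mouse phantom sizes
#'
#' For each organ and body size, runs a pure-123I simulation with the source
#' confined to that organ under the full acquisition pipeline (energy
#' blurring, attenuation/scatter medium, detector-assembly scatter) and, by
#' default, the standard corrections (DEW scatter then analytic attenuation
#' correction), mirroring how acquisition software processes both windows.
#' Reports the per-cell e123 mean, SD and coefficient of variation.
#'
#' @param sizes Tibble with `radius_cm` and `length_cm` columns (default: the
#'   1.5/4, 2/5, 2/6, 2.5/7, 3/8 grid).
#' @param organs Organ names to sweep.
#' @param corrected Apply DEW + attenuation corrections (default `TRUE`).
#' @inheritParams sweep_imaging_conditions
#' @return Tibble with one row per organ x size: `organ`, `radius_cm`,
#'   `length_cm`, `e123`, `e123_sd`, `e123_cov`, and the per-rep ratios in the
#'   list column `per_rep`.
#' @export
sweep_mouse_sizes <- function(sizes = tibble::tibble(
                                radius_cm = c(1.5, 2, 2, 2.5, 3),
                                length_cm = c(4, 5, 6, 7, 8)),
                              organs = c("spleen", "liver", "heart", "kidney"),
                              n_decays = 1e6, n_reps = 5, seed = 1,
                              mode = "MGP", corrected = TRUE,
                              voxel_mm = 0.5) {
  sys <- spect_system(mode, housing = TRUE, blur = TRUE)
  out <- list()
  for (i in seq_len(nrow(sizes))) {
    base <- mouse_phantom(sizes$radius_cm[i], sizes$length_cm[i],
                          organ_activities = list(), voxel_mm = voxel_mm)
    for (organ in organs) {
      ph <- set_organ_activity(base, organ, c(I123 = 1))
      cfg <- scenario_config(ph, sys, n_decays = c(I123 = n_decays),
                             n_reps = n_reps,
                             seed = seed + 37L * i + match(organ, organs),
                             dew = corrected, attenuation = corrected,
                             att_organ = organ)
      res <- run_scenario(cfg)
      g <- glance(res)
      td <- tidy(res)
      out[[length(out) + 1L]] <- tibble::tibble(
        organ = organ, radius_cm = sizes$radius_cm[i],
        length_cm = sizes$length_cm[i],
        e123 = g$e123, e123_sd = g$e123_sd, e123_cov = g$e123_cov,
        per_rep = list(td$LO123 / td$HI123))
    }
  }
  dplyr::bind_rows(out)
}

parse_ratio <- function(r) {
  p <- as.numeric(strsplit(r, ":", fixed = TRUE)[[1]])
  stopifnot(length(p) == 2, all(p > 0))
  p
}

#' Stripping accuracy across activity ratios and imaging conditions
#'
#' The central validation sweep: a mouse phantom with the kidney as emission
#' source, 123I:125I activity ratios of 1:1, 1:2 and 2:1, under three
#' conditions: ideal (no scatter medium), attenuation + scatter without
#' corrections, and attenuation + scatter with DEW and attenuation
#' corrections. The overlap ratio e123 is pre-computed once per detector mode
#' from pure-123I kidney runs under the corrected pipeline (the calibration a
#' practitioner would carry over from reference scans), then applied to every
#' mixed run via the stripping formula; the relative estimation error r125 is
#' reported per repetition.
#'
#' @param ratios Character activity ratios `"123I:125I"`.
#' @param conditions Subset of `c("ideal", "uncorrected", "corrected")`.
#' @param modes Detector modes to sweep (default both pinhole systems).
#' @param n_decays123 123I decays per rep; 125I decays scale with the ratio.
#' @param body_radius_cm,body_length_cm Mouse body size (default 2/6: 4 cm
#'   wide, 6 cm long).
#' @inheritParams sweep_imaging_conditions
#' @return Tibble with one row per mode x ratio x condition x rep: `r125`,
#'   `abs_r125`, the stripped `estimate125` and `actual125`, and the
#'   calibration `e123_cal` used. 2 x 3 x 3 cells by default.
#' @export
sweep_activity_ratios <- function(ratios = c("1:1", "1:2", "2:1"),
                                  conditions = c("ideal", "uncorrected",
                                                 "corrected"),
                                  modes = c("MGP", "MWB"),
                                  n_decays123 = 1e6, n_reps = 5, seed = 1,
                                  body_radius_cm = 2, body_length_cm = 6,
                                  voxel_mm = 0.5) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  base <- mouse_phantom(body_radius_cm, body_length_cm,
                        organ_activities = list(), voxel_mm = voxel_mm)
  vac <- base; vac$material[] <- MATERIALS[["vacuum"]]
  out <- list()
  for (mi in seq_along(modes)) {
    mode <- modes[mi]
    # pre-computed calibration: pure 123I, corrected A+S pipeline
    ph_cal <- set_organ_activity(base, "kidney", c(I123 = 1))
    cal_cfg <- scenario_config(ph_cal,
                               spect_system(mode, housing = TRUE, blur = TRUE),
                               n_decays = c(I123 = n_decays123),
                               n_reps = n_reps, seed = seed + 1000L * mi,
                               dew = TRUE, attenuation = TRUE,
                               att_organ = "kidney")
    e123_cal <- estimate_e123(run_scenario(cal_cfg)$counts)$e123
    for (ri in seq_along(ratios)) {
      p <- parse_ratio(ratios[ri])
      nd <- c(I123 = n_decays123, I125 = round(n_decays123 * p[2] / p[1]))
      add_cell <- function(cond, counts) {
        st <- strip_overlap(counts, e123_cal)
        tibble::tibble(
          mode = mode, ratio = ratios[ri], condition = cond,
          rep = st$rep, r125 = st$r125, abs_r125 = abs(st$r125),
          estimate125 = st$estimate125, actual125 = st$actual125,
          e123_cal = e123_cal)
      }
      if ("ideal" %in% conditions) {
        ph <- set_organ_activity(vac, "kidney", c(I123 = 1, I125 = 1))
        cfg <- scenario_config(ph, spect_system(mode, housing = FALSE,
                                                blur = TRUE),
                               n_decays = nd, n_reps = n_reps,
                               seed = seed + 1000L * mi + 7L)
        out[[length(out) + 1L]] <- add_cell("ideal", run_scenario(cfg)$counts)
      }
      if (any(c("uncorrected", "corrected") %in% conditions)) {
        # one acquisition, processed with and without corrections -- the
        # corrected/uncorrected contrast is paired on the same data
        ph <- set_organ_activity(base, "kidney", c(I123 = 1, I125 = 1))
        cfg <- scenario_config(ph, spect_system(mode, housing = TRUE,
                                                blur = TRUE),
                               n_decays = nd, n_reps = n_reps,
                               seed = seed + 1000L * mi + 50L,
                               dew = TRUE, attenuation = TRUE,
                               att_organ = "kidney")
        res <- run_scenario(cfg)
        if ("uncorrected" %in% conditions)
          out[[length(out) + 1L]] <- add_cell("uncorrected", res$counts_raw)
        if ("corrected" %in% conditions)
          out[[length(out) + 1L]] <- add_cell("corrected", res$counts)
      }
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = c("ideal", "uncorrected",
                                                "corrected")))
}

#' Write and re-read sweep result tables
#'
#' Results are columnar TSV; `read_results()` reproduces the written tibble
#' exactly (full-precision round trip). `report_results()` writes the table
#' and, when the result carries window totals or r125 columns, a summary
#' figure alongside it.
#'
#' @param results A sweep result tibble (nonempty).
#' @param path Output TSV path (for `report_results()`, figures are written
#'   next to it).
#' @return `path`, invisibly (`read_results()` returns the tibble).
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  results <- results[, !vapply(results, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(results, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname write_results
#' @export
report_results <- function(results, path) {
  write_results(results, path)
  fig <- NULL
  if (all(c("condition", "LO", "HI") %in% names(results)))
    fig <- plot_window_totals(results)
  else if ("abs_r125" %in% names(results))
    fig <- plot_stripping_error(results)
  if (!is.null(fig))
    ggplot2::ggsave(sub("\\.tsv$", ".png", path), fig,
                    width = 7, height = 4.5, dpi = 150)
  invisible(path)
}
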