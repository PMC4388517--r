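#' Stacked window totals across imaging conditions
#'
#' Bar chart of mean low- and high-window totals per condition (the classic
#' condition-ladder summary), with the per-condition e123 printed above the
#' bars.
#'
#' @param results Output of [sweep_imaging_conditions()] (or any tibble with
#'   `condition`, `LO`, `HI`, `e123` columns).
#' @return A ggplot object.
#' @export
plot_window_totals <- function(results) {
  sm <- results |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(LO = mean(.data$LO), HI = mean(.data$HI),
                     e123 = mean(.data$e123), .groups = "drop") |>
    tidyr::pivot_longer(c("LO", "HI"), names_to = "window",
                        values_to = "counts")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$condition, y = .data$counts,
                                   fill = .data$window)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::geom_text(
      data = dplyr::distinct(sm, .data$condition, .data$e123),
      ggplot2::aes(x = .data$condition, y = Inf,
                   label = sprintf("e123 = %.2f", .data$e123)),
      vjust = 1.5, inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = NULL, y = "window counts (weighted)",
                  fill = "window") +
    ggplot2::theme_minimal()
}

#' Stripping error across ratios and conditions
#'
#' @param results Output of [sweep_activity_ratios()].
#' @return A ggplot object: |r125| per ratio, faceted by mode and condition.
#' @export
plot_stripping_error <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$ratio, y = .data$abs_r125)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          fill = "steelblue") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::facet_grid(mode ~ condition) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "123I : 125I activity ratio",
                  y = "|r125| (relative estimation error)") +
    ggplot2::theme_minimal()
}

#' Detected energy spectra per isotope
#'
#' @param events Event tibble from [detect_events()].
#' @param bin_kev Histogram bin width, keV.
#' @param head Head blurring to apply (see [spectrum_histogram()]).
#' @param max_kev Upper energy limit shown.
#' @return A ggplot object with one trace per isotope.
#' @export
plot_spectrum <- function(events, bin_kev = 2, head = "LO", max_kev = 200) {
  h <- spectrum_histogram(events, bin_kev = bin_kev, head = head,
                          max_kev = max_kev)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$energy_kev, y = .data$counts,
                                  colour = .data$isotope)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "energy (keV)", y = "counts (weighted)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scenario_result <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(td[, c("rep", "LO", "HI")], c("LO", "HI"),
                              names_to = "window", values_to = "counts")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$rep), y = .data$counts,
                                     fill = .data$window)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "repetition", y = "window counts (weighted)") +
    ggplot2::theme_minimal()
}
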