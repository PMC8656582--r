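# ggplot2 figures for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted calibration curve
#'
#' Standards (mean +/- SD) with the fitted saturating response.
#'
#' @param object an [fit_calibration()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fw_calibration <- function(object, ...) {
  st <- object$standards
  grid <- tibble::tibble(density = seq(0, object$rho_max, length.out = 200))
  grid$intensity <- cal_intensity(object, grid$density)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$density,
                                   y = .data$mean_intensity)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$intensity), colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_intensity - .data$sd_intensity,
      ymax = .data$mean_intensity + .data$sd_intensity)) +
    ggplot2::labs(x = expression("areal density (pg/" * mu * m^2 * ")"),
                  y = "mean intensity (counts)",
                  title = "Calibration standards and fitted response") +
    ggplot2::theme_minimal()
}

#' Occupancy histogram
#'
#' Detected cells per well as a percentage bar chart.
#'
#' @param observations a [count_cells_per_well()] table.
#' @param max_cells wells with more cells are pooled into one bin.
#' @return A ggplot.
#' @export
plot_occupancy <- function(observations, max_cells = 3) {
  df <- dplyr::count(
    observations,
    cells = factor(pmin(.data$n_cells_detected, max_cells),
                   levels = 0:max_cells,
                   labels = c(0:(max_cells - 1), paste0(max_cells, "+"))))
  df$pct <- 100 * df$n / sum(df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cells, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "cells per well", y = "% of wells",
                  title = "Well occupancy") +
    ggplot2::theme_minimal()
}

#' Per-phase secretion boxplot
#'
#' The assay's boxplot convention: box = first/third quartile, band = median,
#' square = mean; one box per phase over secreting wells.
#'
#' @param series a [build_timeseries()] table.
#' @param secretors_only restrict to wells above background in each phase.
#' @return A ggplot.
#' @export
plot_secretion <- function(series, secretors_only = TRUE) {
  long <- tidyr::pivot_longer(
    dplyr::select(series, "well_id", dplyr::starts_with("rate_"),
                  dplyr::starts_with("above_bg_")),
    dplyr::starts_with("rate_"), names_to = "phase", names_prefix = "rate_",
    values_to = "rate")
  if (secretors_only) {
    ab <- tidyr::pivot_longer(
      dplyr::select(series, "well_id", dplyr::starts_with("above_bg_")),
      dplyr::starts_with("above_bg_"), names_to = "phase",
      names_prefix = "above_bg_", values_to = "above")
    long <- dplyr::left_join(long[, c("well_id", "phase", "rate")], ab,
                             by = c("well_id", "phase"))
    long <- long[long$above %in% TRUE, ]
  }
  long <- long[!is.na(long$rate), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$rate)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 15, size = 2) +
    ggplot2::labs(x = "phase", y = "secretion (pg/cell/day)",
                  title = "Per-cell secretion by phase") +
    ggplot2::theme_minimal()
}

#' Per-well secretion trajectories coloured by response phenotype
#'
#' @param series a [classify_response()] table.
#' @param max_wells trajectories drawn (sampled deterministically).
#' @return A ggplot.
#' @export
plot_timeseries <- function(series, max_wells = 200) {
  s <- series[!is.na(series$rate_t0), ]
  if (nrow(s) > max_wells) {
    s <- s[unique(round(seq(1, nrow(s), length.out = max_wells))), ]
  }
  long <- tidyr::pivot_longer(
    dplyr::select(s, "well_id", "response", dplyr::starts_with("rate_")),
    dplyr::starts_with("rate_"), names_to = "phase", names_prefix = "rate_",
    values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$rate,
                                     group = .data$well_id,
                                     colour = .data$response)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "phase", y = "secretion (pg/cell/day)",
                  colour = "response",
                  title = "Single-well secretion trajectories") +
    ggplot2::theme_minimal()
}
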