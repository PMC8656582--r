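# Calibration-curve fitting/inversion, empty-well background statistics, and
# conversion of membrane ROI intensities to absolute mass and per-cell rates.

#' Measure calibration-standard spots
#'
#' Samples the pixels of each standard disc (eroded slightly from the rim to
#' avoid edge mixing) and summarises them.
#'
#' @param mosaic calibration membrane [fw_mosaic()].
#' @param truth standards table with `density`, `x_um`, `y_um`, `radius_um`
#'   (as produced by [render_calibration_series()]).
#' @return Tibble: `density`, `mean_intensity`, `sd_intensity`, `n_pixels`.
#' @export
measure_calibration_spots <- function(mosaic, truth) {
  s <- mosaic$pixel_size_um
  px <- mosaic$pixels
  xs <- (seq_len(ncol(px)) - 0.5) * s
  ys <- (seq_len(nrow(px)) - 0.5) * s
  purrr::map_dfr(seq_len(nrow(truth)), function(k) {
    r <- truth$radius_um[k] - 2 * s
    sel <- outer((ys - truth$y_um[k])^2, (xs - truth$x_um[k])^2, "+") <= r^2
    v <- px[sel]
    tibble::tibble(density = truth$density[k], mean_intensity = mean(v),
                   sd_intensity = stats::sd(v), n_pixels = length(v))
  })
}

#' Fit the saturating calibration curve
#'
#' Least-squares fit of the monotone saturating model
#' `I(rho) = I_bg + I_max * rho / (rho_half + rho)` to the standards, by
#' Levenberg-Marquardt. The fit is refused when fewer than 4 distinct
#' densities (including 0) are supplied, when mean intensities are
#' non-monotone beyond noise, or when the fitted `I_max`/`rho_half` are
#' non-positive.
#'
#' @param standards tibble with `density`, `mean_intensity` and optionally
#'   `sd_intensity`, `n_pixels` (from [measure_calibration_spots()]).
#' @return An object of class `fw_calibration`: fitted parameters `i_bg`,
#'   `i_max`, `rho_half`, the standards table, residuals, and the valid
#'   density range.
#' @export
fit_calibration <- function(standards) {
  st <- dplyr::arrange(standards, .data$density)
  if (length(unique(st$density)) < 4 || !any(st$density == 0)) {
    fw_stop("need >= 4 distinct standard densities including 0",
            class = "fw_contract_error")
  }
  noise_sd <- if ("sd_intensity" %in% names(st) && all(!is.na(st$sd_intensity))) {
    stats::median(st$sd_intensity / sqrt(pmax(st$n_pixels %||% 1, 1)))
  } else {
    stats::sd(diff(st$mean_intensity)) / 10
  }
  if (any(diff(st$mean_intensity) < -6 * max(noise_sd, 1e-9))) {
    fw_stop("standard mean intensities are non-monotone beyond noise; ",
            "refusing to fit", class = "fw_fit_error")
  }
  i_bg0 <- st$mean_intensity[st$density == 0][1]
  i_max0 <- max(st$mean_intensity) - i_bg0
  rho_half0 <- stats::median(st$density[st$density > 0])
  fit <- minpack.lm::nlsLM(
    mean_intensity ~ i_bg + i_max * density / (rho_half + density),
    data = st,
    start = list(i_bg = i_bg0, i_max = i_max0 * 1.5, rho_half = rho_half0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf["i_max"] <= 0 || cf["rho_half"] <= 0) {
    fw_stop("calibration fit degenerate: I_max and rho_half must be positive",
            class = "fw_fit_error")
  }
  structure(list(i_bg = unname(cf["i_bg"]), i_max = unname(cf["i_max"]),
                 rho_half = unname(cf["rho_half"]),
                 rho_max = max(st$density), standards = st,
                 residuals = unname(stats::residuals(fit)),
                 sigma = sqrt(mean(stats::residuals(fit)^2))),
            class = "fw_calibration")
}

#' @export
print.fw_calibration <- function(x, ...) {
  cat(sprintf(
    "<fw_calibration> I(rho) = %.1f + %.1f rho/(%.4g + rho), valid rho in [0, %g] pg/um^2\n",
    x$i_bg, x$i_max, x$rho_half, x$rho_max))
  invisible(x)
}

#' Evaluate or invert a fitted calibration curve
#'
#' `cal_intensity()` maps areal density to expected intensity;
#' `cal_density()` is its exact inverse on the curve's open intensity range.
#'
#' @param curve an [fit_calibration()] result.
#' @param rho areal densities, pg/um^2.
#' @return Intensities (counts) / densities (pg/um^2).
#' @export
cal_intensity <- function(curve, rho) {
  curve$i_bg + curve$i_max * rho / (curve$rho_half + rho)
}

#' @rdname cal_intensity
#' @param intensity measured mean intensities, counts.
#' @export
cal_density <- function(curve, intensity) {
  d <- intensity - curve$i_bg
  out <- curve$rho_half * d / (curve$i_max - d)
  out[d <= 0] <- 0
  out
}

#' Empty-well background statistics
#'
#' Mean and SD of membrane ROI mean intensities over wells in which the cell
#' detector found no cell. At least `min_wells` empty wells are required (the
#' assay's rule of >50 empty wells across the chip); the floor can be lowered
#' explicitly for small test chips, which is logged with a message.
#'
#' @param spots ROI measurement table from [assign_spots_to_wells()].
#' @param observations per-well cell counts ([count_cells_per_well()] output
#'   for the loading image).
#' @param min_wells minimum number of empty wells.
#' @return List of class `fw_background`: `mean_intensity`, `sd_intensity`,
#'   `n_wells_used`.
#' @export
estimate_background <- function(spots, observations, min_wells = 50) {
  empty <- observations$well_id[observations$n_cells_detected == 0L]
  v <- spots$mean_intensity[spots$well_id %in% empty]
  v <- v[!is.na(v)]
  if (length(v) < min_wells) {
    fw_stop("insufficient background: only ", length(v),
            " empty wells available (need >= ", min_wells, ")",
            class = "fw_background_error")
  }
  if (min_wells < 50) {
    message("estimate_background: empty-well floor lowered to ", min_wells)
  }
  structure(list(mean_intensity = mean(v), sd_intensity = stats::sd(v),
                 n_wells_used = length(v)), class = "fw_background")
}

#' Quantify membrane spots to absolute mass and per-cell rates
#'
#' Inverts each well's mean ROI intensity through the calibration curve to an
#' areal density, multiplies by the ROI area to get mass (pg), and derives the
#' per-cell secretion rate from the well's detected cell count and the phase
#' duration. Intensities at or below the fitted background map to mass 0
#' (`censored = "below_range"`); intensities at or beyond the curve's ceiling
#' are censored at the valid-range ceiling (`"above_range"`). A well is
#' `above_background` when its ROI mean exceeds the empty-well mean by
#' `k_bg` empty-well SDs.
#'
#' @param spots ROI measurements ([assign_spots_to_wells()]).
#' @param curve an [fit_calibration()] result.
#' @param background an [estimate_background()] result.
#' @param observations per-well counts used for per-cell rates (loading-image
#'   detection); wells with 0 detected cells get `NA` rates.
#' @param duration_h capture duration of the phase, hours.
#' @param k_bg SD multiplier of the above-background rule.
#' @return Tibble: `well_id`, `mean_intensity`, `roi_area_um2`, `mass_pg`,
#'   `n_cells`, `rate_pg_per_cell_day`, `above_background`, `censored`.
#' @export
quantify_spots <- function(spots, curve, background, observations,
                           duration_h = 24, k_bg = 3) {
  stopifnot(inherits(curve, "fw_calibration"),
            inherits(background, "fw_background"))
  df <- dplyr::left_join(
    spots, dplyr::select(observations, "well_id",
                         n_cells = "n_cells_detected"),
    by = "well_id")
  area <- pi * df$radius_um^2
  i_ceiling <- cal_intensity(curve, curve$rho_max)
  rho <- cal_density(curve, pmin(df$mean_intensity, i_ceiling))
  censored <- dplyr::case_when(
    df$mean_intensity >= i_ceiling ~ "above_range",
    df$mean_intensity <= curve$i_bg ~ "below_range",
    TRUE ~ "none")
  rho[censored == "above_range"] <- curve$rho_max
  mass <- rho * area
  thr <- background$mean_intensity + k_bg * background$sd_intensity
  tibble::tibble(
    well_id = df$well_id,
    mean_intensity = df$mean_intensity,
    roi_area_um2 = area,
    mass_pg = mass,
    n_cells = df$n_cells,
    rate_pg_per_cell_day = ifelse(df$n_cells >= 1,
                                  mass / df$n_cells / (duration_h / 24),
                                  NA_real_),
    above_background = df$mean_intensity > thr,
    censored = censored)
}

#' Per-cell secretion rate
#'
#' @param mass_pg captured mass, pg.
#' @param n_cells cells in the well (must be >= 1).
#' @param duration_h capture duration, hours.
#' @return pg/cell/day.
#' @examples
#' per_cell_rate(9.6, 2, 24) # 4.8
#' @export
per_cell_rate <- function(mass_pg, n_cells, duration_h = 24) {
  if (any(n_cells < 1)) {
    fw_stop("per-cell rate undefined for empty wells (n_cells must be >= 1)",
            class = "fw_contract_error")
  }
  stopifnot(all(duration_h > 0))
  mass_pg / n_cells / (duration_h / 24)
}
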