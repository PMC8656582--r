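# Forward rendering: fluorescence channels, capture membranes, calibration
# standards, and the detector-facing noise model.

#' Imaging noise model
#'
#' Rendered images are `background` counts plus signal, optionally passed
#' through Poisson shot noise (unit gain), plus Gaussian read noise, rounded
#' and clipped to the unsigned 16-bit range.
#'
#' @param background constant camera background, counts.
#' @param read_sd Gaussian read-noise standard deviation, counts.
#' @param shot logical; apply Poisson shot noise to the expected counts.
#' @return An object of class `fw_noise`.
#' @export
fw_noise <- function(background = 500, read_sd = 30, shot = TRUE) {
  stopifnot(background >= 0, read_sd >= 0)
  structure(list(background = background, read_sd = read_sd, shot = shot),
            class = "fw_noise")
}

#' Forward calibration model
#'
#' Monotone saturating response of the labelled membrane: the intensity above
#' camera background for areal density `rho` (pg/um^2) is
#' `i_max * rho / (rho_half + rho)`.
#'
#' @param i_max saturation intensity above background, counts.
#' @param rho_half density at half saturation, pg/um^2.
#' @return An object of class `fw_cal_forward`.
#' @export
fw_cal_forward <- function(i_max = 40000, rho_half = 0.02) {
  stopifnot(i_max > 0, rho_half > 0)
  structure(list(i_max = i_max, rho_half = rho_half),
            class = "fw_cal_forward")
}

# intensity above background for areal density rho
cal_delta <- function(forward, rho) {
  forward$i_max * rho / (forward$rho_half + rho)
}

# Apply the noise model to a noiseless expected image (counts incl. background)
apply_noise <- function(px, noise, seed) {
  old <- .Random.seed_exists()
  set.seed(seed)
  if (noise$shot) {
    v <- stats::rpois(length(px), lambda = as.vector(px))
  } else {
    v <- as.vector(px)
  }
  if (noise$read_sd > 0) v <- v + stats::rnorm(length(px), sd = noise$read_sd)
  .restore_seed(old)
  n_clipped <- sum(v > 65535)
  v <- pmin(pmax(round(v), 0), 65535)
  out <- matrix(v, nrow = nrow(px))
  attr(out, "n_clipped") <- n_clipped
  out
}

blank_canvas <- function(geometry) {
  d <- geom_image_dim(geometry)
  matrix(0, nrow = d["rows"], ncol = d["cols"])
}

# Patch of a Gaussian blob (peak `amplitude`) at (x_um, y_um): returns the
# target row/col ranges and the patch values, so the caller can accumulate
# into its own (unshared, hence in-place-modifiable) canvas.
blob_patch <- function(dim_px, x_um, y_um, sigma_um, amplitude, s) {
  hw <- ceiling(4 * sigma_um / s)
  jc <- x_um / s + 0.5; ic <- y_um / s + 0.5 # 1-based pixel-centre coords
  j <- max(1, floor(jc - hw)):min(dim_px[2], ceiling(jc + hw))
  i <- max(1, floor(ic - hw)):min(dim_px[1], ceiling(ic + hw))
  if (length(i) == 0 || length(j) == 0) return(NULL)
  dx2 <- ((j - jc) * s)^2; dy2 <- ((i - ic) * s)^2
  list(i = i, j = j,
       g = amplitude * exp(-(outer(dy2, dx2, "+")) / (2 * sigma_um^2)))
}

#' Render a cell or dead-cell fluorescence channel
#'
#' One Gaussian blob per cell that is in the requested state at the requested
#' phase. Phase `"loading"` renders every seeded cell as live (the image taken
#' right after well filling, used for occupancy); phases `"t0"`/`"t1"`/`"t2"`
#' use the truth table's alive flags at the end of that 24 h window.
#'
#' @param truth cell-level truth (through [apply_viability()] for the timed
#'   phases; [seed_cells()] output suffices for `"loading"`).
#' @param geometry a [chip_geometry()].
#' @param phase `"loading"`, `"t0"`, `"t1"` or `"t2"`.
#' @param channel `"live"` (calcein) or `"dead"` (ethidium homodimer).
#' @param noise an [fw_noise()].
#' @param blob_sigma_um Gaussian radius of a rendered cell.
#' @param amplitude peak intensity above background of one cell.
#' @param seed integer seed for the noise draw.
#' @return An [fw_mosaic()].
#' @export
render_cell_channel <- function(truth, geometry, phase = "loading",
                                channel = c("live", "dead"),
                                noise = fw_noise(), blob_sigma_um = 6,
                                amplitude = 800, seed = 1L) {
  channel <- match.arg(channel)
  px <- blank_canvas(geometry)
  if (nrow(truth) > 0) {
    sel <- if (phase == "loading") {
      rep(channel == "live", nrow(truth))
    } else {
      alive <- truth[[paste0("alive_", phase)]]
      if (is.null(alive)) {
        fw_stop("truth table lacks alive flags for phase ", phase,
                class = "fw_contract_error")
      }
      if (channel == "live") alive else !alive
    }
    s <- geometry$pixel_size_um
    dp <- dim(px)
    for (k in which(sel)) {
      b <- blob_patch(dp, truth$x_um[k], truth$y_um[k], blob_sigma_um,
                      amplitude, s)
      if (!is.null(b)) px[b$i, b$j] <- px[b$i, b$j] + b$g
    }
  }
  out <- apply_noise(px + noise$background, noise, seed)
  fw_mosaic(out, geometry$pixel_size_um,
            meta = list(phase = phase, channel = channel,
                        n_clipped = attr(out, "n_clipped")))
}

#' Render a capture-membrane image for one phase
#'
#' Each well contributes one isotropic Gaussian spot at its (rigidly
#' transformed) pore position. The spot's total captured mass is the sum of
#' its live cells' rates times `duration_h / 24`; the spot is scaled so that
#' the mean intensity over the well's measurement ROI equals the forward
#' calibration at `mass / ROI area` — i.e. rendering and calibration-curve
#' inversion are exact inverses up to noise and quantisation.
#'
#' @param truth cell-level truth through [apply_viability()].
#' @param geometry a [chip_geometry()].
#' @param phase `"t0"`, `"t1"` or `"t2"`.
#' @param cal_forward an [fw_cal_forward()].
#' @param noise an [fw_noise()].
#' @param duration_h capture duration of the phase, hours.
#' @param transform optional rigid transform (list with `dx_um`, `dy_um`,
#'   `theta_deg`) mapping chip coordinates into the membrane image, e.g. a
#'   mounting offset; `NULL` = identity.
#' @param spot_sigma_um Gaussian radius of a diffusion-broadened spot.
#' @param seed integer seed for the noise draw.
#' @return An [fw_mosaic()]; `meta$n_clipped` counts saturated pixels (a
#'   warning is raised when any spot hits the 16-bit ceiling).
#' @export
render_membrane <- function(truth, geometry, phase, cal_forward = fw_cal_forward(),
                            noise = fw_noise(), duration_h = 24,
                            transform = NULL, spot_sigma_um = 20, seed = 1L) {
  rate_col <- paste0("rate_", phase)
  if (!rate_col %in% names(truth)) {
    fw_stop("truth table lacks ", rate_col, class = "fw_contract_error")
  }
  wells <- dplyr::summarise(dplyr::group_by(truth, .data$well_id),
                            mass_pg = sum(.data[[rate_col]]) * duration_h / 24,
                            .groups = "drop")
  wells <- wells[wells$mass_pg > 0, ]
  centers <- well_centers(geometry)
  px <- blank_canvas(geometry)
  s <- geometry$pixel_size_um
  roi <- geometry$spot_roi_radius_um
  roi_area <- pi * roi^2
  if (nrow(wells) > 0) {
    m <- match(wells$well_id, centers$well_id)
    pos <- transform_points(transform, centers$x_um[m], centers$y_um[m],
                            geometry)
    hw <- ceiling(max(4 * spot_sigma_um, roi + 2 * s) / s)
    for (k in seq_len(nrow(wells))) {
      jc <- pos$x[k] / s + 0.5; ic <- pos$y[k] / s + 0.5
      j <- max(1, floor(jc - hw)):min(ncol(px), ceiling(jc + hw))
      i <- max(1, floor(ic - hw)):min(nrow(px), ceiling(ic + hw))
      dx2 <- ((j - jc) * s)^2; dy2 <- ((i - ic) * s)^2
      g <- exp(-(outer(dy2, dx2, "+")) / (2 * spot_sigma_um^2))
      in_roi <- outer(dy2, dx2, "+") <= roi^2
      unit_mean <- mean(g[in_roi])
      delta <- cal_delta(cal_forward, wells$mass_pg[k] / roi_area)
      px[i, j] <- px[i, j] + (delta / unit_mean) * g
    }
  }
  out <- apply_noise(px + noise$background, noise, seed)
  if (attr(out, "n_clipped") > 0) {
    warning(sprintf("membrane %s: %d pixel(s) clipped at the 16-bit ceiling",
                    phase, attr(out, "n_clipped")), call. = FALSE)
  }
  fw_mosaic(out, s, meta = list(phase = phase, channel = "membrane",
                                transform = transform,
                                n_clipped = attr(out, "n_clipped")))
}

#' Render the calibration-standard membrane
#'
#' One uniform disc per standard density, mimicking 1 uL drops of known
#' protein concentration spread on the membrane; disc intensity is background
#' plus the forward model at that density, plus noise.
#'
#' @param densities areal densities of the standards, pg/um^2 (must include 0).
#' @param cal_forward an [fw_cal_forward()].
#' @param noise an [fw_noise()].
#' @param pixel_size_um micrometres per pixel of the calibration image.
#' @param disc_radius_um radius of each rendered standard disc.
#' @param seed integer seed for the noise draw.
#' @return List with `mosaic` (an [fw_mosaic()]) and `truth` (tibble: `spot`,
#'   `density`, `x_um`, `y_um`, `radius_um`).
#' @export
render_calibration_series <- function(densities, cal_forward = fw_cal_forward(),
                                      noise = fw_noise(), pixel_size_um = 2.5,
                                      disc_radius_um = 150, seed = 1L) {
  stopifnot(all(densities >= 0))
  if (!any(densities == 0)) {
    fw_stop("calibration series must include a zero-density standard",
            class = "fw_config_error")
  }
  n <- length(densities)
  spacing <- 4 * disc_radius_um
  w_um <- n * spacing; h_um <- spacing
  ncols <- ceiling(w_um / pixel_size_um); nrows <- ceiling(h_um / pixel_size_um)
  px <- matrix(0, nrow = nrows, ncol = ncols)
  xs <- (seq_len(ncols) - 0.5) * pixel_size_um
  ys <- (seq_len(nrows) - 0.5) * pixel_size_um
  truth <- tibble::tibble(spot = seq_len(n) - 1L, density = densities,
                          x_um = (seq_len(n) - 0.5) * spacing,
                          y_um = spacing / 2, radius_um = disc_radius_um)
  for (k in seq_len(n)) {
    inside <- outer((ys - truth$y_um[k])^2, (xs - truth$x_um[k])^2, "+") <=
      disc_radius_um^2
    px[inside] <- px[inside] + cal_delta(cal_forward, densities[k])
  }
  out <- apply_noise(px + noise$background, noise, seed)
  list(mosaic = fw_mosaic(out, pixel_size_um,
                          meta = list(phase = "calibration",
                                      channel = "membrane")),
       truth = truth)
}
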