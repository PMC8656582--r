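# Rigid membrane-to-chip registration: spot detection, inlier grid search,
# closed-form rigid refinement, and per-well ROI assignment.

#' Rigid chip-to-membrane transform
#'
#' Translation plus a small rotation about the chip centre, mapping chip-frame
#' coordinates into a membrane image. Membranes are mounted flat against the
#' chip, so scale and shear are not modelled; mounting tolerance bounds the
#' rotation at 5 degrees.
#'
#' @param dx_um,dy_um translation, micrometres.
#' @param theta_deg rotation about the chip centre, degrees.
#' @param residual_um RMS distance between matched spot centroids and
#'   transformed well centres.
#' @param n_inliers number of spot centroids supporting the estimate.
#' @param low_confidence flag set when the residual exceeds pitch/4.
#' @return An object of class `fw_transform`.
#' @export
fw_transform <- function(dx_um = 0, dy_um = 0, theta_deg = 0,
                         residual_um = NA_real_, n_inliers = NA_integer_,
                         low_confidence = FALSE) {
  if (abs(theta_deg) > 5) {
    fw_stop("rotation beyond the 5-degree mounting tolerance",
            class = "fw_config_error")
  }
  structure(list(dx_um = dx_um, dy_um = dy_um, theta_deg = theta_deg,
                 residual_um = residual_um, n_inliers = n_inliers,
                 low_confidence = low_confidence), class = "fw_transform")
}

#' @export
print.fw_transform <- function(x, ...) {
  cat(sprintf(
    "<fw_transform> dx %.2f um, dy %.2f um, theta %.3f deg (residual %.2f um, %s inliers)%s\n",
    x$dx_um, x$dy_um, x$theta_deg, x$residual_um,
    ifelse(is.na(x$n_inliers), "?", x$n_inliers),
    if (isTRUE(x$low_confidence)) " [low confidence]" else ""))
  invisible(x)
}

chip_center <- function(geometry) {
  c(x = geometry$n_cols * geometry$pitch_um / 2,
    y = geometry$n_rows * geometry$pitch_um / 2)
}

# Forward-map chip-frame points into the membrane frame. transform may be an
# fw_transform, a bare list with the same fields, or NULL (identity).
transform_points <- function(transform, x, y, geometry) {
  if (is.null(transform)) return(list(x = x, y = y))
  th <- (transform$theta_deg %||% 0) * pi / 180
  ctr <- chip_center(geometry)
  xr <- cos(th) * (x - ctr["x"]) - sin(th) * (y - ctr["y"]) + ctr["x"]
  yr <- sin(th) * (x - ctr["x"]) + cos(th) * (y - ctr["y"]) + ctr["y"]
  list(x = unname(xr + (transform$dx_um %||% 0)),
       y = unname(yr + (transform$dy_um %||% 0)))
}

# Inverse map: membrane frame -> chip frame.
invert_points <- function(transform, x, y, geometry) {
  if (is.null(transform)) return(list(x = x, y = y))
  th <- (transform$theta_deg %||% 0) * pi / 180
  ctr <- chip_center(geometry)
  xs <- x - (transform$dx_um %||% 0) - ctr["x"]
  ys <- y - (transform$dy_um %||% 0) - ctr["y"]
  list(x = unname(cos(th) * xs + sin(th) * ys + ctr["x"]),
       y = unname(-sin(th) * xs + cos(th) * ys + ctr["y"]))
}

#' Detect membrane spot centroids
#'
#' Gaussian smoothing at the spot scale, robust global threshold
#' (median + k * SD estimated from the median absolute deviation), connected
#' components, intensity-weighted centroids.
#'
#' @param mosaic membrane [fw_mosaic()].
#' @param smooth_sigma_um smoothing radius (default: half a spot).
#' @param k threshold multiplier over the robust background SD.
#' @param min_area_px discard components smaller than this.
#' @return Tibble: `x_um`, `y_um`, `area_px`, `peak`.
#' @export
detect_spot_centroids <- function(mosaic, smooth_sigma_um = 10, k = 6,
                                  min_area_px = 20) {
  s <- mosaic$pixel_size_um
  sm <- EBImage::gblur(mosaic$pixels, sigma = max(smooth_sigma_um / s, 0.5))
  # background level/SD from the lower quantiles, which bright spots cannot
  # contaminate even on densely occupied chips
  q <- stats::quantile(sm, c(0.25, 0.45), names = FALSE)
  sdr <- (q[2] - q[1]) / (stats::qnorm(0.45) - stats::qnorm(0.25))
  med <- q[1] - stats::qnorm(0.25) * sdr
  thr <- med + k * max(sdr, 1e-6)
  lab <- EBImage::bwlabel(sm > thr)
  idx <- which(lab > 0)
  if (length(idx) == 0) {
    return(tibble::tibble(x_um = double(), y_um = double(),
                          area_px = integer(), peak = double()))
  }
  lv <- as.integer(lab[idx])
  wi <- sm[idx] - med
  ii <- ((idx - 1) %% nrow(sm)) + 1
  jj <- ((idx - 1) %/% nrow(sm)) + 1
  wsum <- rowsum(wi, lv)
  xw <- rowsum(wi * ((jj - 0.5) * s), lv) / wsum
  yw <- rowsum(wi * ((ii - 0.5) * s), lv) / wsum
  area <- as.integer(rowsum(rep(1L, length(lv)), lv))
  peak <- vapply(split(wi, lv), max, numeric(1))
  out <- tibble::tibble(x_um = as.vector(xw), y_um = as.vector(yw),
                        area_px = area, peak = as.vector(peak))
  out[out$area_px >= min_area_px, ]
}

score_candidates <- function(cand, pts, geometry, tol) {
  vapply(seq_len(nrow(cand)), function(i) {
    tr <- list(dx_um = cand$dx[i], dy_um = cand$dy[i], theta_deg = cand$th[i])
    p <- invert_points(tr, pts$x_um, pts$y_um, geometry)
    id <- map_point_to_well(geometry, p$x, p$y, tolerance_um = tol)
    sum(!is.na(id))
  }, numeric(1))
}

# Closed-form rigid fit (rotation about chip centre) on matched pairs.
rigid_fit <- function(wx, wy, sx, sy, geometry) {
  ctr <- chip_center(geometry)
  ax <- wx - ctr["x"]; ay <- wy - ctr["y"]
  bx <- sx - ctr["x"]; by <- sy - ctr["y"]
  axc <- ax - mean(ax); ayc <- ay - mean(ay)
  bxc <- bx - mean(bx); byc <- by - mean(by)
  th <- atan2(sum(axc * byc - ayc * bxc), sum(axc * bxc + ayc * byc))
  rx <- cos(th) * mean(ax) - sin(th) * mean(ay)
  ry <- sin(th) * mean(ax) + cos(th) * mean(ay)
  list(theta_deg = th * 180 / pi,
       dx_um = unname(mean(bx) - rx), dy_um = unname(mean(by) - ry))
}

#' Estimate the membrane-to-chip rigid alignment
#'
#' Detects spot centroids, then searches translation and small rotation for
#' the transform maximising the number of centroids landing within pitch/4 of
#' a well centre (coarse grid, local refinement), and polishes the winner with
#' a closed-form rigid least-squares fit on the inlier matches. Inlier
#' counting (not least squares) drives the search so that missing spots
#' (non-secretors) and merged spots cannot drag the optimum.
#'
#' @param mosaic membrane [fw_mosaic()].
#' @param geometry a [chip_geometry()].
#' @param max_shift_um half-width of the translation search window.
#' @param max_theta_deg half-width of the rotation search window.
#' @param min_spots minimum number of detected spots required.
#' @param ... passed to [detect_spot_centroids()].
#' @return An [fw_transform()] with residual and inlier count;
#'   `low_confidence` is set when the RMS residual exceeds pitch/4.
#' @export
estimate_alignment <- function(mosaic, geometry, max_shift_um = 40,
                               max_theta_deg = 1, min_spots = 50, ...) {
  pts <- detect_spot_centroids(mosaic, ...)
  if (nrow(pts) < min_spots) {
    fw_stop("insufficient signal: only ", nrow(pts),
            " spot(s) detected (need >= ", min_spots, ")",
            class = "fw_signal_error")
  }
  search <- pts
  if (nrow(search) > 1500) {
    search <- search[order(-search$peak)[seq_len(1500)], ]
  }
  tol <- geometry$pitch_um / 4
  coarse <- expand.grid(dx = seq(-max_shift_um, max_shift_um, by = 10),
                        dy = seq(-max_shift_um, max_shift_um, by = 10),
                        th = seq(-max_theta_deg, max_theta_deg, by = 0.25))
  sc <- score_candidates(coarse, search, geometry, tol)
  best <- coarse[which.max(sc), ]
  fine <- expand.grid(dx = best$dx + seq(-8, 8, by = 2),
                      dy = best$dy + seq(-8, 8, by = 2),
                      th = best$th + seq(-0.2, 0.2, by = 0.05))
  sc <- score_candidates(fine, search, geometry, tol)
  best <- fine[which.max(sc), ]
  tr <- list(dx_um = best$dx, dy_um = best$dy, theta_deg = best$th)
  ctrs <- well_centers(geometry)
  # two rounds of match -> closed-form rigid fit on all detected spots
  for (it in 1:2) {
    p <- invert_points(tr, pts$x_um, pts$y_um, geometry)
    id <- map_point_to_well(geometry, p$x, p$y, tolerance_um = tol)
    ok <- !is.na(id)
    if (sum(ok) < 3) break
    m <- match(id[ok], ctrs$well_id)
    tr <- rigid_fit(ctrs$x_um[m], ctrs$y_um[m], pts$x_um[ok], pts$y_um[ok],
                    geometry)
  }
  p <- invert_points(tr, pts$x_um, pts$y_um, geometry)
  id <- map_point_to_well(geometry, p$x, p$y, tolerance_um = tol)
  ok <- !is.na(id)
  m <- match(id[ok], ctrs$well_id)
  pf <- transform_points(tr, ctrs$x_um[m], ctrs$y_um[m], geometry)
  res <- sqrt(mean((pf$x - pts$x_um[ok])^2 + (pf$y - pts$y_um[ok])^2))
  fw_transform(tr$dx_um, tr$dy_um, tr$theta_deg, residual_um = res,
               n_inliers = sum(ok), low_confidence = res > tol)
}

#' Assign measurement ROIs to every well and measure them
#'
#' Purely geometric: every well receives a disc ROI of radius
#' `spot_roi_radius_um` centred at its transformed pore position — wells
#' without a visible spot included, since background estimation and
#' below-background calls need them. The mean intensity over each ROI's
#' in-image pixels is measured on the membrane mosaic.
#'
#' @param mosaic membrane [fw_mosaic()].
#' @param transform an [fw_transform()] (or `NULL` for identity).
#' @param geometry a [chip_geometry()].
#' @return Tibble: `well_id`, ROI centre `x_um`, `y_um`, `radius_um`,
#'   `mean_intensity`, `n_pixels`.
#' @export
assign_spots_to_wells <- function(mosaic, transform, geometry) {
  ctrs <- well_centers(geometry)
  pos <- transform_points(transform, ctrs$x_um, ctrs$y_um, geometry)
  r <- geometry$spot_roi_radius_um
  s <- mosaic$pixel_size_um
  px <- mosaic$pixels
  hw <- ceiling(r / s) + 1L
  mi <- numeric(nrow(ctrs)); np <- integer(nrow(ctrs))
  for (k in seq_len(nrow(ctrs))) {
    jc <- pos$x[k] / s + 0.5; ic <- pos$y[k] / s + 0.5
    j <- max(1, floor(jc - hw)):min(ncol(px), ceiling(jc + hw))
    i <- max(1, floor(ic - hw)):min(nrow(px), ceiling(ic + hw))
    if (length(i) == 0 || length(j) == 0) { mi[k] <- NA; next }
    sel <- outer(((i - ic) * s)^2, ((j - jc) * s)^2, "+") <= r^2
    vals <- px[i, j][sel]
    mi[k] <- mean(vals); np[k] <- length(vals)
  }
  tibble::tibble(well_id = ctrs$well_id, x_um = pos$x, y_um = pos$y,
                 radius_um = r, mean_intensity = mi, n_pixels = np)
}
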