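# Per-well cell counting and live/dead viability from fluorescence channels.

#' Cell-detector parameters
#'
#' Defaults are tuned against simulator truth tables at the default rendering
#' signal-to-noise and are all overridable. The threshold is local: each
#' well's background mean and SD come from the border annulus of its own ROI,
#' which makes counts invariant to global intensity scaling up to the
#' threshold rule.
#'
#' @param smooth_sigma_um Gaussian pre-smoothing radius (about one cell
#'   radius).
#' @param k threshold multiplier: background mean + k * SD of the annulus.
#' @param margin_um margin subtracted from pitch/2 to form the well ROI disc.
#' @param annulus_inner_frac inner radius of the background annulus as a
#'   fraction of the ROI radius.
#' @param sd_floor_frac floor on the annulus SD estimate, as a fraction of
#'   the annulus mean: guards the threshold against a degenerate (near-zero)
#'   SD on noise-free input while keeping counts exactly invariant to global
#'   intensity scaling.
#' @param nominal_cell_area_um2 expected suprathreshold footprint of one cell.
#' @param min_area_frac components below this fraction of nominal area are
#'   discarded as noise.
#' @param split_factor components above this multiple of nominal area are
#'   counted as ceiling(area / nominal) touching cells.
#' @return List of class `fw_detect_params`.
#' @export
fw_detect_params <- function(smooth_sigma_um = 3, k = 4, margin_um = 5,
                             annulus_inner_frac = 0.8, sd_floor_frac = 0.022,
                             nominal_cell_area_um2 = 800,
                             min_area_frac = 0.25, split_factor = 1.8) {
  structure(list(smooth_sigma_um = smooth_sigma_um, k = k,
                 margin_um = margin_um,
                 annulus_inner_frac = annulus_inner_frac,
                 sd_floor_frac = sd_floor_frac,
                 nominal_cell_area_um2 = nominal_cell_area_um2,
                 min_area_frac = min_area_frac, split_factor = split_factor),
            class = "fw_detect_params")
}

# per-pixel well index (1-based) and squared distance to own well centre
pixel_well_frame <- function(geometry, dim_px, s) {
  p <- geometry$pitch_um
  x <- (seq_len(dim_px[2]) - 0.5) * s
  y <- (seq_len(dim_px[1]) - 0.5) * s
  colw <- pmin(pmax(floor(x / p), 0), geometry$n_cols - 1L)
  roww <- pmin(pmax(floor(y / p), 0), geometry$n_rows - 1L)
  dx2 <- (x - (colw + 0.5) * p)^2
  dy2 <- (y - (roww + 0.5) * p)^2
  widx <- outer(roww * geometry$n_cols, colw, "+") + 1L # 1-based well index
  r2 <- outer(dy2, dx2, "+")
  list(widx = widx, r2 = r2)
}

#' Count cells per well
#'
#' Detects fluorescent cell blobs and assigns them to wells: Gaussian
#' smoothing, per-well threshold at annulus background mean + k SD, connected
#' components inside the well ROI disc, minimum-area rejection, and a
#' touching-cell split that counts oversized components as
#' ceiling(area / nominal cell area).
#'
#' @param mosaic a chip-frame [fw_mosaic()] (cell or dead channel).
#' @param geometry a [chip_geometry()].
#' @param params an [fw_detect_params()].
#' @return Tibble with one row per well: `well_id`, `n_cells_detected`,
#'   `mean_intensity` (mean raw intensity over detected pixels; `NA` if none),
#'   `saturated` flag.
#' @export
count_cells_per_well <- function(mosaic, geometry,
                                 params = fw_detect_params()) {
  s <- mosaic$pixel_size_um
  d <- geom_image_dim(geometry)
  if (nrow(mosaic$pixels) != d["rows"] || ncol(mosaic$pixels) != d["cols"]) {
    fw_stop("mosaic dimensions do not match the geometry frame (",
            nrow(mosaic$pixels), " x ", ncol(mosaic$pixels), " vs expected ",
            d["rows"], " x ", d["cols"], ")", class = "fw_contract_error")
  }
  p <- geometry$pitch_um
  n_wells <- geometry$n_rows * geometry$n_cols
  sm <- EBImage::gblur(mosaic$pixels, sigma = max(params$smooth_sigma_um / s, 0.5))
  fr <- pixel_well_frame(geometry, dim(sm), s)
  r_roi <- p / 2 - params$margin_um
  ann <- fr$r2 >= (params$annulus_inner_frac * r_roi)^2 & fr$r2 <= r_roi^2
  wi_ann <- fr$widx[ann]; v_ann <- sm[ann]
  nk <- tabulate(wi_ann, nbins = n_wells)
  mu <- rowsum(v_ann, wi_ann)[, 1] / pmax(nk[sort(unique(wi_ann))], 1)
  mu_full <- numeric(n_wells); mu_full[sort(unique(wi_ann))] <- mu
  s2 <- rowsum(v_ann^2, wi_ann)[, 1]
  uw <- sort(unique(wi_ann))
  var_full <- numeric(n_wells)
  var_full[uw] <- pmax(s2 / pmax(nk[uw], 1) - mu^2, 0)
  thr <- mu_full + params$k * pmax(sqrt(var_full),
                                   params$sd_floor_frac * mu_full)
  mask <- (sm > matrix(thr[fr$widx], nrow = nrow(sm))) & (fr$r2 <= r_roi^2)
  lab <- EBImage::bwlabel(mask)
  counts <- integer(n_wells)
  mean_int <- rep(NA_real_, n_wells)
  idx <- which(lab > 0)
  if (length(idx) > 0) {
    lv <- as.integer(lab[idx])
    area_px <- tabulate(lv)
    wsum <- rowsum(sm[idx] - mu_full[fr$widx[idx]], lv)[, 1]
    ii <- ((idx - 1) %% nrow(sm)) + 1
    jj <- ((idx - 1) %/% nrow(sm)) + 1
    cx <- rowsum((sm[idx]) * (jj - 0.5) * s, lv)[, 1] / rowsum(sm[idx], lv)[, 1]
    cy <- rowsum((sm[idx]) * (ii - 0.5) * s, lv)[, 1] / rowsum(sm[idx], lv)[, 1]
    wid <- map_point_to_well(geometry, cx, cy, tolerance_um = p / 2)
    area_um2 <- area_px * s^2
    nom <- params$nominal_cell_area_um2
    n_of <- ifelse(area_um2 < params$min_area_frac * nom, 0L,
                   ifelse(area_um2 <= params$split_factor * nom, 1L,
                          as.integer(ceiling(area_um2 / nom))))
    keep <- !is.na(wid) & n_of > 0L
    if (any(keep)) {
      widx1 <- wid[keep] + 1L
      counts[seq_len(n_wells)] <- 0L
      cc <- rowsum(n_of[keep], widx1)
      counts[as.integer(rownames(cc))] <- cc[, 1]
      raw_mean <- rowsum(mosaic$pixels[idx], lv)[, 1] / area_px
      mm <- rowsum(raw_mean[keep] * n_of[keep], widx1)[, 1] /
        rowsum(n_of[keep], widx1)[, 1]
      mean_int[as.integer(rownames(cc))] <- mm
    }
  }
  sat <- rowsum(as.numeric(mosaic$pixels[fr$r2 <= r_roi^2] >= 65535),
                fr$widx[fr$r2 <= r_roi^2])
  sat_full <- logical(n_wells)
  sat_full[as.integer(rownames(sat))] <- sat[, 1] > 0
  tibble::tibble(well_id = seq_len(n_wells) - 1L,
                 n_cells_detected = counts, mean_intensity = mean_int,
                 saturated = sat_full)
}

#' Per-well viability from the live/dead channel pair
#'
#' Runs the cell detector independently on the calcein (live) and ethidium
#' homodimer (dead) channels of one phase. A well is "viable-occupied" when at
#' least one live cell is detected.
#'
#' @param live_mosaic,dead_mosaic same-phase chip-frame mosaics.
#' @param geometry a [chip_geometry()].
#' @param params an [fw_detect_params()].
#' @return Tibble: `well_id`, `n_live`, `n_dead`, `n_cells_detected`
#'   (= n_live + n_dead), `viable_occupied`.
#' @export
viability_per_well <- function(live_mosaic, dead_mosaic, geometry,
                               params = fw_detect_params()) {
  live <- count_cells_per_well(live_mosaic, geometry, params)
  dead <- count_cells_per_well(dead_mosaic, geometry, params)
  tibble::tibble(well_id = live$well_id,
                 n_live = live$n_cells_detected,
                 n_dead = dead$n_cells_detected,
                 n_cells_detected = live$n_cells_detected +
                   dead$n_cells_detected,
                 viable_occupied = live$n_cells_detected >= 1L)
}

#' Cohort viability
#'
#' Total live cells over total counted cells, as a percentage.
#'
#' @param observations output of [viability_per_well()] (needs `n_live` and
#'   `n_dead`).
#' @return Viability percentage (scalar).
#' @export
cohort_viability <- function(observations) {
  tot <- sum(observations$n_live) + sum(observations$n_dead)
  if (tot == 0) {
    fw_stop("cohort viability is undefined: no cells counted",
            class = "fw_degenerate_error")
  }
  100 * sum(observations$n_live) / tot
}
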