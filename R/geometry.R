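#' Microwell chip geometry
#'
#' Defines the coordinate frame every image in a run is interpreted in: a
#' regular `n_rows` x `n_cols` lattice of wells at `pitch_um` spacing over the
#' chip's active area. Continuous coordinates are micrometres with the origin
#' at the chip's top-left corner; well (0,0) has its centre at
#' (pitch/2, pitch/2); well ids are row-major and 0-based. Pixel (i,j)
#' (0-based) covers the half-open square
#' \[j*s, (j+1)*s) x \[i*s, (i+1)*s) micrometres, s = `pixel_size_um`.
#'
#' The default preset reconstructs the assay's chip: 6400 wells on an
#' 8 x 8 mm surface, factorised as 80 x 80 at 100 um pitch (the only square
#' factorisation consistent with a square active area and single-cell wells;
#' the true commercial pitch is not public).
#'
#' @param n_rows,n_cols wells per side.
#' @param pitch_um centre-to-centre well spacing, micrometres.
#' @param pore_diameter_um bottom-pore diameter, micrometres.
#' @param active_area_mm chip active area (width, height), millimetres.
#' @param pixel_size_um micrometres per image pixel.
#' @param tile_grid image tile mosaic layout, (rows, cols).
#' @param spot_roi_radius_um radius of the disc over which a membrane spot is
#'   measured; must stay below `pitch_um / 2` so neighbouring ROIs never
#'   overlap.
#' @return An object of class `fw_geometry`.
#' @examples
#' geom <- chip_geometry()
#' nrow(well_centers(geom))  # 6400
#' @export
chip_geometry <- function(n_rows = 80, n_cols = 80, pitch_um = 100,
                          pore_diameter_um = 5, active_area_mm = c(8, 8),
                          pixel_size_um = 2.5, tile_grid = c(10, 10),
                          spot_roi_radius_um = 35) {
  g <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            pitch_um = pitch_um, pore_diameter_um = pore_diameter_um,
            active_area_mm = active_area_mm, pixel_size_um = pixel_size_um,
            tile_grid = as.integer(tile_grid),
            spot_roi_radius_um = spot_roi_radius_um)
  if (g$n_rows < 1 || g$n_cols < 1) {
    fw_stop("chip must have at least one row and one column of wells",
            class = "fw_config_error")
  }
  if (pitch_um * g$n_cols > active_area_mm[1] * 1000 + 1e-9) {
    fw_stop("invariant violated: pitch_um * n_cols exceeds active width (",
            pitch_um * g$n_cols, " > ", active_area_mm[1] * 1000, " um)",
            class = "fw_config_error")
  }
  if (pitch_um * g$n_rows > active_area_mm[2] * 1000 + 1e-9) {
    fw_stop("invariant violated: pitch_um * n_rows exceeds active height",
            class = "fw_config_error")
  }
  if (spot_roi_radius_um >= pitch_um / 2) {
    fw_stop("invariant violated: spot_roi_radius_um (", spot_roi_radius_um,
            ") must be < pitch_um / 2 (", pitch_um / 2,
            ") so adjacent ROIs never overlap", class = "fw_config_error")
  }
  structure(g, class = "fw_geometry")
}

#' @export
print.fw_geometry <- function(x, ...) {
  cat(sprintf("<fw_geometry> %d x %d wells (%d), pitch %g um, %g um/px\n",
              x$n_rows, x$n_cols, x$n_rows * x$n_cols, x$pitch_um,
              x$pixel_size_um))
  invisible(x)
}

# image dimensions implied by the geometry (pixels, rows x cols)
geom_image_dim <- function(geometry) {
  c(rows = as.integer(round(geometry$n_rows * geometry$pitch_um /
                              geometry$pixel_size_um)),
    cols = as.integer(round(geometry$n_cols * geometry$pitch_um /
                              geometry$pixel_size_um)))
}

#' Well centres of a chip
#'
#' @param geometry a [chip_geometry()].
#' @return A tibble with one row per well: `well_id` (row-major, 0-based),
#'   `row`, `col`, and centre coordinates `x_um`, `y_um`.
#' @export
well_centers <- function(geometry) {
  stopifnot(inherits(geometry, "fw_geometry"))
  grid <- expand.grid(col = seq_len(geometry$n_cols) - 1L,
                      row = seq_len(geometry$n_rows) - 1L)
  tibble::tibble(
    well_id = grid$row * geometry$n_cols + grid$col,
    row = grid$row, col = grid$col,
    x_um = (grid$col + 0.5) * geometry$pitch_um,
    y_um = (grid$row + 0.5) * geometry$pitch_um
  )
}

#' Map continuous chip coordinates to well ids
#'
#' Returns, for each point, the id of the well whose centre is nearest, or
#' `NA` when the nearest centre lies farther than `tolerance_um`. The inverse
#' of [well_centers()] on exact centres.
#'
#' @param geometry a [chip_geometry()].
#' @param x_um,y_um point coordinates (vectorised), micrometres.
#' @param tolerance_um maximum accepted distance to the nearest well centre;
#'   must not exceed `pitch_um / 2`.
#' @return Integer vector of well ids (`NA` where out of tolerance).
#' @export
map_point_to_well <- function(geometry, x_um, y_um,
                              tolerance_um = geometry$pitch_um / 2) {
  stopifnot(inherits(geometry, "fw_geometry"), length(x_um) == length(y_um))
  if (tolerance_um > geometry$pitch_um / 2 + 1e-9) {
    fw_stop("tolerance_um must be <= pitch_um / 2", class = "fw_config_error")
  }
  p <- geometry$pitch_um
  col <- pmin(pmax(round(x_um / p - 0.5), 0), geometry$n_cols - 1L)
  row <- pmin(pmax(round(y_um / p - 0.5), 0), geometry$n_rows - 1L)
  d <- sqrt((x_um - (col + 0.5) * p)^2 + (y_um - (row + 0.5) * p)^2)
  id <- as.integer(row * geometry$n_cols + col)
  id[d > tolerance_um] <- NA_integer_
  id
}

#' Serialise / restore a geometry for the run manifest
#' @param geometry a [chip_geometry()].
#' @return `geometry_to_list()`: a plain list; `geometry_from_list()`: an
#'   `fw_geometry`.
#' @export
geometry_to_list <- function(geometry) {
  unclass(geometry)
}

#' @rdname geometry_to_list
#' @param x a list as produced by `geometry_to_list()`.
#' @export
geometry_from_list <- function(x) {
  do.call(chip_geometry, x)
}
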