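# Mosaic container and lossless tiled-TIFF IO with a YAML run manifest.

#' Single-channel chip-frame image
#'
#' A light container for one grayscale 16-bit image in the chip coordinate
#' frame: a numeric matrix of integer counts (row = y, col = x), the pixel
#' size, the chip-frame position of pixel (0,0)'s corner, and provenance.
#'
#' @param pixels numeric matrix of counts in \[0, 65535\].
#' @param pixel_size_um micrometres per pixel.
#' @param origin_um chip-frame coordinates (x, y) of the top-left pixel corner.
#' @param meta free-form provenance list (phase, channel, source tiles).
#' @return An object of class `fw_mosaic`.
#' @export
fw_mosaic <- function(pixels, pixel_size_um, origin_um = c(0, 0),
                      meta = list()) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 origin_um = origin_um, meta = meta), class = "fw_mosaic")
}

#' @export
print.fw_mosaic <- function(x, ...) {
  cat(sprintf("<fw_mosaic> %d x %d px @ %g um/px (%s/%s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              x$meta$phase %||% "?", x$meta$channel %||% "?"))
  invisible(x)
}

read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    fw_stop("manifest not found: ", manifest_path, class = "fw_io_error")
  }
  yaml::read_yaml(manifest_path)
}

write_manifest <- function(manifest, manifest_path) {
  tmp <- paste0(manifest_path, ".tmp")
  yaml::write_yaml(manifest, tmp)
  file.rename(tmp, manifest_path) # atomic update
  invisible(manifest_path)
}

tile_name <- function(phase, channel, r, c) {
  sprintf("%s_%s_r%d_c%d.tif", phase, channel, r, c)
}

#' Write a mosaic as an uncompressed 16-bit tiled TIFF grid
#'
#' Splits the mosaic into the geometry's tile grid (tiles abut exactly; no
#' stitching overlap) and records every tile in the run manifest, which is
#' updated atomically. Round trips losslessly for any 16-bit content.
#'
#' @param mosaic an [fw_mosaic()].
#' @param manifest_path path to `manifest.yaml` (created if absent); tiles are
#'   written next to it.
#' @param phase,channel labels naming this image in the manifest.
#' @param tile_grid (rows, cols) of tiles; mosaic dimensions must be divisible
#'   by it.
#' @return Invisibly, the tile file names.
#' @export
write_tile_grid <- function(mosaic, manifest_path, phase, channel,
                            tile_grid = c(1, 1)) {
  px <- mosaic$pixels
  tg <- as.integer(tile_grid)
  if (nrow(px) %% tg[1] != 0 || ncol(px) %% tg[2] != 0) {
    fw_stop("mosaic dimensions (", nrow(px), " x ", ncol(px),
            ") are not divisible by the tile grid (", tg[1], " x ", tg[2],
            ")", class = "fw_contract_error")
  }
  th <- nrow(px) %/% tg[1]; tw <- ncol(px) %/% tg[2]
  dir <- dirname(manifest_path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- if (file.exists(manifest_path)) read_manifest(manifest_path) else list()
  man$tiles <- man$tiles %||% list()
  # drop any previous tiles for this phase/channel
  keep <- vapply(man$tiles, function(t) {
    !(identical(t$phase, phase) && identical(t$channel, channel))
  }, logical(1))
  man$tiles <- man$tiles[keep]
  files <- character(0)
  for (r in seq_len(tg[1])) {
    for (cc in seq_len(tg[2])) {
      tile <- px[((r - 1) * th + 1):(r * th), ((cc - 1) * tw + 1):(cc * tw),
                 drop = FALSE]
      f <- tile_name(phase, channel, r - 1L, cc - 1L)
      tiff::writeTIFF(pmin(pmax(tile, 0), 65535) / 65535,
                      file.path(dir, f), bits.per.sample = 16L,
                      compression = "none")
      man$tiles[[length(man$tiles) + 1L]] <-
        list(phase = phase, channel = channel, row = r - 1L, col = cc - 1L,
             file = f)
      files <- c(files, f)
    }
  }
  man$pixel_size_um <- mosaic$pixel_size_um
  write_manifest(man, manifest_path)
  invisible(files)
}

#' Assemble a tiled image from a run manifest
#'
#' Tiles are placed by their (row, col) manifest position; they abut exactly.
#' A missing or dimension-mismatched tile is an error naming the file.
#'
#' @param manifest_path path to the run's `manifest.yaml`.
#' @param phase,channel which image to assemble.
#' @return An [fw_mosaic()] of integer counts in \[0, 65535\].
#' @export
read_tile_grid <- function(manifest_path, phase, channel) {
  man <- read_manifest(manifest_path)
  dir <- dirname(manifest_path)
  tiles <- Filter(function(t) identical(t$phase, phase) &&
                    identical(t$channel, channel), man$tiles %||% list())
  if (length(tiles) == 0) {
    fw_stop("no tiles for phase '", phase, "' channel '", channel,
            "' in manifest", class = "fw_lookup_error")
  }
  rows <- vapply(tiles, function(t) t$row, numeric(1))
  cols <- vapply(tiles, function(t) t$col, numeric(1))
  key <- paste(rows, cols)
  if (anyDuplicated(key)) {
    fw_stop("manifest lists a tile position more than once for ", phase, "/",
            channel, class = "fw_format_error")
  }
  ngrid <- c(max(rows) + 1L, max(cols) + 1L)
  if (length(tiles) != prod(ngrid)) {
    missing <- setdiff(paste(rep(0:(ngrid[1] - 1), each = ngrid[2]),
                             rep(0:(ngrid[2] - 1), ngrid[1])), key)
    fw_stop("missing tile(s) at grid position(s): ",
            paste(missing, collapse = "; "), class = "fw_io_error")
  }
  first <- read_tile(file.path(dir, tiles[[1]]$file))
  th <- nrow(first); tw <- ncol(first)
  px <- matrix(0, nrow = th * ngrid[1], ncol = tw * ngrid[2])
  for (t in tiles) {
    m <- read_tile(file.path(dir, t$file))
    if (nrow(m) != th || ncol(m) != tw) {
      fw_stop("tile dimension mismatch in ", t$file, " (", nrow(m), " x ",
              ncol(m), ", expected ", th, " x ", tw, ")",
              class = "fw_format_error")
    }
    px[(t$row * th + 1):((t$row + 1) * th),
       (t$col * tw + 1):((t$col + 1) * tw)] <- m
  }
  fw_mosaic(px, man$pixel_size_um %||% 1,
            meta = list(phase = phase, channel = channel,
                        source = vapply(tiles, function(t) t$file,
                                        character(1))))
}

read_tile <- function(path) {
  if (!file.exists(path)) {
    fw_stop("tile file missing: ", path, class = "fw_io_error")
  }
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  storage.mode(m) <- "double"
  m
}
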