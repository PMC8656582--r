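# Whole-experiment forward simulation: truth tables, all rendered images,
# calibration standards, and a YAML manifest, written as one run directory.

#' Default calibration-standard densities
#'
#' Areal densities of 1 uL drops at 0, 15, 30, 75, 150 and 300 ug/mL spread
#' over a 4e6 um^2 spot: 300 ug/mL * 1 uL = 3e5 pg over 4e6 um^2 =
#' 0.075 pg/um^2 at the top of the range.
#'
#' @return Numeric vector of densities, pg/um^2.
#' @export
default_calibration_densities <- function() {
  c(0, 15, 30, 75, 150, 300) * 1e3 / 4e6
}

random_offset <- function(seed, max_shift = 30, max_theta = 0.3) {
  old <- .Random.seed_exists()
  set.seed(seed)
  out <- list(dx_um = stats::runif(1, -max_shift, max_shift),
              dy_um = stats::runif(1, -max_shift, max_shift),
              theta_deg = stats::runif(1, -max_theta, max_theta))
  .restore_seed(old)
  out
}

#' Simulate a complete microwell fluorospot experiment
#'
#' Composes the forward model end to end: cells are seeded into wells, given
#' rates and phenotypes, passed through the viability model, and rendered as a
#' loading-time cell image, per-phase live/dead channel pairs, per-phase
#' capture membranes (each with its own injected mounting offset), and a
#' calibration-standard membrane. Everything is written to `out_dir` as
#' uncompressed 16-bit TIFF tiles plus `manifest.yaml`, `truth_cells.csv` and
#' `truth_calibration.csv`, and is bit-identical for identical configuration
#' and seed.
#'
#' @param out_dir run directory (created).
#' @param geometry a [chip_geometry()].
#' @param population an [population_model()] or preset name for [fw_preset()].
#' @param drug_arm `"enzalutamide"` or `"abiraterone"` (phase t2).
#' @param noise an [fw_noise()].
#' @param cal_forward an [fw_cal_forward()].
#' @param phases timed phases to render (subset of `t0`, `t1`, `t2`).
#' @param render_membranes,render_dead switch off unneeded channels for
#'   cheaper runs.
#' @param duration_h capture duration per phase, hours.
#' @param membrane_offsets optional named list (per phase) of injected rigid
#'   offsets (`dx_um`, `dy_um`, `theta_deg`); default draws small random
#'   mounting offsets from the seed.
#' @param calibration_densities standard densities, pg/um^2.
#' @param cell_amplitude,blob_sigma_um,spot_sigma_um rendering parameters.
#' @param seed master seed; every stage derives a named substream from it.
#' @return Invisibly, a list: `out_dir`, `manifest` path, `truth`,
#'   `cal_truth`, `offsets`.
#' @export
simulate_experiment <- function(out_dir,
                                geometry = chip_geometry(),
                                population = "lncap-basal",
                                drug_arm = c("enzalutamide", "abiraterone"),
                                noise = fw_noise(),
                                cal_forward = fw_cal_forward(),
                                phases = c("t0", "t1", "t2"),
                                render_membranes = TRUE,
                                render_dead = TRUE,
                                duration_h = 24,
                                membrane_offsets = NULL,
                                calibration_densities =
                                  default_calibration_densities(),
                                cell_amplitude = 800,
                                blob_sigma_um = 6,
                                spot_sigma_um = 20,
                                seed = 1L) {
  drug_arm <- match.arg(drug_arm)
  if (is.character(population)) population <- fw_preset(population, drug_arm)
  stopifnot(inherits(population, "fw_population"))
  phases <- match.arg(phases, c("t0", "t1", "t2"), several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  if (file.exists(manifest_path)) file.remove(manifest_path)

  truth <- seed_cells(geometry, population$occupancy_probs,
                      seed = substream_seed(seed, "seed_cells"))
  truth <- assign_rates(truth, population,
                        seed = substream_seed(seed, "assign_rates"))
  truth <- apply_viability(truth, population,
                           seed = substream_seed(seed, "viability"))
  utils::write.csv(truth, file.path(out_dir, "truth_cells.csv"),
                   row.names = FALSE)

  tg <- geometry$tile_grid
  put <- function(mosaic, phase, channel) {
    write_tile_grid(mosaic, manifest_path, phase, channel, tile_grid = tg)
  }
  put(render_cell_channel(truth, geometry, "loading", "live", noise,
                          blob_sigma_um, cell_amplitude,
                          seed = substream_seed(seed, "img_loading")),
      "loading", "cell")

  offsets <- list()
  for (ph in phases) {
    put(render_cell_channel(truth, geometry, ph, "live", noise,
                            blob_sigma_um, cell_amplitude,
                            seed = substream_seed(seed, paste0("img_", ph, "_live"))),
        ph, "cell")
    if (render_dead) {
      put(render_cell_channel(truth, geometry, ph, "dead", noise,
                              blob_sigma_um, cell_amplitude,
                              seed = substream_seed(seed, paste0("img_", ph, "_dead"))),
          ph, "dead")
    }
    if (render_membranes) {
      off <- membrane_offsets[[ph]] %||%
        random_offset(substream_seed(seed, paste0("offset_", ph)))
      offsets[[ph]] <- off
      put(render_membrane(truth, geometry, ph, cal_forward, noise, duration_h,
                          transform = off, spot_sigma_um = spot_sigma_um,
                          seed = substream_seed(seed, paste0("img_", ph, "_mem"))),
          ph, "membrane")
    }
  }

  cal <- NULL
  if (render_membranes) {
    cal <- render_calibration_series(
      calibration_densities, cal_forward, noise,
      pixel_size_um = geometry$pixel_size_um,
      seed = substream_seed(seed, "img_calibration"))
    write_tile_grid(cal$mosaic, manifest_path, "calibration", "membrane",
                    tile_grid = c(1, 1))
    utils::write.csv(cal$truth, file.path(out_dir, "truth_calibration.csv"),
                     row.names = FALSE)
  }

  drug_of <- c(t0 = "none", t1 = "R1881 2 nM",
               t2 = paste(drug_arm, if (drug_arm == "enzalutamide")
                 "2 uM" else "1 uM"))
  man <- read_manifest(manifest_path)
  man$geometry <- geometry_to_list(geometry)
  man$phases <- lapply(c("loading", phases), function(ph) {
    list(name = ph, duration_h = if (ph == "loading") 0 else duration_h,
         drug = if (ph == "loading") "none" else unname(drug_of[ph]))
  })
  man$drug_arm <- drug_arm
  man$noise <- unclass(noise)
  man$seed <- seed
  man$injected_offsets <- offsets # simulator truth, not read by the analysis
  man$cal_forward <- unclass(cal_forward)
  write_manifest(man, manifest_path)
  invisible(list(out_dir = out_dir, manifest = manifest_path, truth = truth,
                 cal_truth = if (is.null(cal)) NULL else cal$truth,
                 offsets = offsets))
}
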