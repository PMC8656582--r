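# Shared fixtures: small chips, quiet simulation wrappers, and a lazy cache
# so expensive simulated runs are built once per session.

test_geom <- function(n = 20, tile = c(2, 2)) {
  chip_geometry(n_rows = n, n_cols = n, active_area_mm = c(n / 10, n / 10),
                tile_grid = tile)
}

noise_off <- function(background = 500) {
  fw_noise(background = background, read_sd = 0, shot = FALSE)
}

# memoised expensive runs shared between test blocks
.fw_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fw_cache)) {
    assign(key, force(expr), envir = .fw_cache)
  }
  get(key, envir = .fw_cache)
}

sim_and_analyze <- function(key, ..., min_bg_wells = 50, min_spots = 50,
                            analyze = TRUE) {
  cached(key, {
    d <- file.path(tempdir(), paste0("fwrun_", key))
    sim <- simulate_experiment(d, ...)
    run <- if (analyze) {
      suppressWarnings(analyze_experiment(d, min_bg_wells = min_bg_wells,
                                          min_spots = min_spots,
                                          write_outputs = FALSE))
    } else NULL
    list(sim = sim, run = run, dir = d)
  })
}
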