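test_that("calibration fit recovers the forward parameters", {
  cal <- render_calibration_series(default_calibration_densities(),
                                   noise = noise_off(), seed = 3)
  curve <- fit_calibration(measure_calibration_spots(cal$mosaic, cal$truth))
  expect_lt(abs(curve$i_bg - 500) / 500, 0.005)
  expect_lt(abs(curve$i_max - 40000) / 40000, 0.005)
  expect_lt(abs(curve$rho_half - 0.02) / 0.02, 0.005)
  # tidiers expose the parameters
  td <- tidy(curve)
  expect_equal(td$term, c("i_bg", "i_max", "rho_half"))
  expect_equal(glance(curve)$n_standards, 6)
  # exact closed-form inverse on the valid range
  rho <- c(0.001, 0.01, 0.05)
  expect_equal(cal_density(curve, cal_intensity(curve, rho)), rho,
               tolerance = 1e-10)
  expect_true(all(diff(cal_density(curve, seq(400, 30000, by = 100))) >= 0))
})

test_that("degenerate standard sets are refused", {
  st <- tibble::tibble(density = c(0, 0.01, 0.02),
                       mean_intensity = c(500, 1000, 1500))
  expect_error(fit_calibration(st), class = "fw_contract_error")
  st4 <- tibble::tibble(density = c(0, 0.01, 0.02, 0.04),
                        mean_intensity = c(500, 9000, 2000, 12000),
                        sd_intensity = rep(10, 4), n_pixels = rep(400, 4))
  expect_error(fit_calibration(st4), "non-monotone", class = "fw_fit_error")
})

test_that("background statistics demand enough empty wells", {
  spots <- tibble::tibble(well_id = 0:99,
                          mean_intensity = rnorm(100, 500, 1.5))
  obs <- tibble::tibble(well_id = 0:99,
                        n_cells_detected = c(rep(0L, 49), rep(1L, 51)))
  expect_error(estimate_background(spots, obs), "49",
               class = "fw_background_error")
  obs$n_cells_detected[50] <- 0L
  bg <- estimate_background(spots, obs)
  expect_equal(bg$n_wells_used, 50)
  expect_lt(abs(bg$mean_intensity - 500), 3 * 1.5 / sqrt(50))
})

test_that("quantification inverts rendering within 2% (noise off)", {
  g <- test_geom(10, tile = c(1, 1))
  m <- population_model(viability = c(t0 = 1, t1 = 1, t2 = 1),
                        secreting_fraction_t0 = 1)
  tr <- apply_viability(assign_rates(seed_cells(g, c(0.3, 0.7, 0, 0), 61),
                                     m, 62), m, 63)
  mem <- render_membrane(tr, g, "t0", noise = noise_off(), seed = 1)
  cal <- render_calibration_series(default_calibration_densities(),
                                   noise = noise_off(), seed = 2)
  curve <- fit_calibration(measure_calibration_spots(cal$mosaic, cal$truth))
  spots <- assign_spots_to_wells(mem, NULL, g)
  live <- render_cell_channel(tr, g, "loading", "live", noise_off(), seed = 3)
  obs <- count_cells_per_well(live, g)
  bg <- estimate_background(spots, obs, min_wells = 10)
  q <- quantify_spots(spots, curve, bg, obs)
  tw <- truth_wells(tr, g)
  occ <- tw$n_cells > 0
  expect_lt(max(abs(q$mass_pg[occ] - tw$well_rate_t0[occ]) /
                  tw$well_rate_t0[occ]), 0.02)
  expect_true(all(q$above_background[occ]))
  # empty wells: mass 0, censored below range, not above background
  expect_true(all(q$mass_pg[!occ] == 0 | q$mean_intensity[!occ] > curve$i_bg))
  expect_true(all(!q$above_background[!occ] | q$mass_pg[!occ] < 0.05))
})

test_that("censoring marks the curve's range boundaries", {
  curve <- structure(list(i_bg = 500, i_max = 40000, rho_half = 0.02,
                          rho_max = 0.075, standards = NULL, residuals = NULL,
                          sigma = 0), class = "fw_calibration")
  bg <- structure(list(mean_intensity = 500, sd_intensity = 1,
                       n_wells_used = 60), class = "fw_background")
  spots <- tibble::tibble(well_id = 0:2, x_um = 0, y_um = 0, radius_um = 35,
                          mean_intensity = c(500, 60000, 2000),
                          n_pixels = 600)
  obs <- tibble::tibble(well_id = 0:2, n_cells_detected = 1L)
  q <- quantify_spots(spots, curve, bg, obs)
  expect_equal(q$censored, c("below_range", "above_range", "none"))
  expect_equal(q$mass_pg[1], 0)
  expect_equal(q$mass_pg[2], 0.075 * pi * 35^2)
  expect_false(q$above_background[1])
})

test_that("per-cell rate arithmetic and homogeneity", {
  expect_equal(per_cell_rate(9.6, 2, 24), 4.8)
  expect_equal(per_cell_rate(5, 1, 12), 10)
  expect_equal(per_cell_rate(2 * 7.3, 2 * 1, 24), per_cell_rate(7.3, 1, 24))
  expect_error(per_cell_rate(1, 0, 24), class = "fw_contract_error")
})
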