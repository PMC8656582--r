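test_that("blank images yield zero cells everywhere", {
  g <- test_geom(6)
  mos <- fw_mosaic(matrix(500, 240, 240), 2.5)
  obs <- count_cells_per_well(mos, g)
  expect_equal(sum(obs$n_cells_detected), 0)
  expect_error(count_cells_per_well(fw_mosaic(matrix(500, 10, 10), 2.5), g),
               class = "fw_contract_error")
})

test_that("noise-free counts equal truth for wells with up to 3 cells", {
  g <- test_geom(12, tile = c(1, 1))
  tr <- seed_cells(g, c(0.1, 0.6, 0.2, 0.1), seed = 21)
  mos <- render_cell_channel(tr, g, "loading", "live", noise_off(), seed = 1)
  obs <- count_cells_per_well(mos, g)
  tw <- truth_wells(tr, g)
  expect_equal(obs$n_cells_detected, tw$n_cells)
})

test_that("default-noise counts match truth in at least 98% of wells", {
  res <- sim_and_analyze("detect_20", geometry = test_geom(20),
                         population = "lncap-basal", phases = "t0",
                         render_membranes = FALSE, render_dead = FALSE,
                         seed = 17, analyze = FALSE)
  mos <- read_tile_grid(res$sim$manifest, "loading", "cell")
  obs <- count_cells_per_well(mos, test_geom(20))
  tw <- truth_wells(res$sim$truth, test_geom(20))
  expect_gte(mean(obs$n_cells_detected == tw$n_cells), 0.98)
})

test_that("counts are invariant to intensity scaling (noise-free)", {
  g <- test_geom(8, tile = c(1, 1))
  tr <- seed_cells(g, c(0, 0.7, 0.3, 0), seed = 5)
  mos <- render_cell_channel(tr, g, "loading", "live", noise_off(), seed = 1)
  scaled <- fw_mosaic(mos$pixels * 3, mos$pixel_size_um)
  expect_equal(count_cells_per_well(scaled, g)$n_cells_detected,
               count_cells_per_well(mos, g)$n_cells_detected)
})

test_that("area-based split handles merged and undersized components", {
  g <- test_geom(4, tile = c(1, 1))
  wc <- well_centers(g)
  # two heavily overlapping blobs in one well: a single merged component
  tr2 <- tibble::tibble(well_id = 5L, cell = 1:2,
                        x_um = wc$x_um[6] + c(-5, 5), y_um = wc$y_um[6])
  mos <- render_cell_channel(tr2, g, "loading", "live", noise_off(), seed = 1)
  # footprint of a single blob at these settings, measured independently
  tr1 <- tibble::tibble(well_id = 5L, cell = 1L, x_um = wc$x_um[6],
                        y_um = wc$y_um[6])
  mos1 <- render_cell_channel(tr1, g, "loading", "live", noise_off(), seed = 1)
  single_area <- sum(mos1$pixels > 500 + 35) * g$pixel_size_um^2
  p <- fw_detect_params(nominal_cell_area_um2 = single_area / 1.9)
  got <- count_cells_per_well(mos, g, p)$n_cells_detected[6]
  expect_gte(got, 2) # split heuristic fires on the merged pair
  # a nominal area far above the blob footprint rejects it as debris
  p_big <- fw_detect_params(nominal_cell_area_um2 = 20 * single_area)
  expect_equal(count_cells_per_well(mos1, g, p_big)$n_cells_detected[6], 0L)
})

test_that("viability counting and cohort viability follow the counts", {
  g <- test_geom(6, tile = c(1, 1))
  tr <- seed_cells(g, c(0, 1, 0, 0), seed = 2)
  live <- render_cell_channel(tr, g, "loading", "live", noise_off(), seed = 1)
  blank <- fw_mosaic(matrix(500, nrow(live$pixels), ncol(live$pixels)), 2.5)
  v <- viability_per_well(live, blank, g)
  expect_equal(cohort_viability(v), 100)
  expect_true(all(v$n_live + v$n_dead == v$n_cells_detected))

  expect_equal(cohort_viability(tibble::tibble(n_live = 85, n_dead = 15)), 85)
  expect_equal(cohort_viability(tibble::tibble(n_live = 0, n_dead = 7)), 0)
  expect_error(cohort_viability(tibble::tibble(n_live = 0, n_dead = 0)),
               class = "fw_degenerate_error")
  # naive-summation oracle on random counts
  set.seed(8)
  rv <- tibble::tibble(n_live = rpois(40, 2), n_dead = rpois(40, 1))
  rv <- rv[rv$n_live + rv$n_dead > 0, ]
  acc <- 0; tot <- 0
  for (i in seq_len(nrow(rv))) {
    acc <- acc + rv$n_live[i]; tot <- tot + rv$n_live[i] + rv$n_dead[i]
  }
  expect_equal(cohort_viability(rv), 100 * acc / tot)
})
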