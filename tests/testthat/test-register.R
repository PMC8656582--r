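# Shared fixture: a mini chip with every well secreting, so membranes carry
# plenty of spots for alignment.
reg_truth <- function(g, seed = 41) {
  m <- population_model(secreting_fraction_t0 = 1,
                        viability = c(t0 = 1, t1 = 1, t2 = 1))
  apply_viability(assign_rates(seed_cells(g, m$occupancy_probs, seed),
                               m, seed + 1), m, seed + 2)
}

test_that("alignment recovers identity and injected transforms", {
  g <- test_geom(16, tile = c(1, 1))
  tr <- reg_truth(g)
  mem0 <- render_membrane(tr, g, "t0", seed = 7)
  est0 <- estimate_alignment(mem0, g)
  expect_lt(abs(est0$dx_um), 1)
  expect_lt(abs(est0$dy_um), 1)
  expect_lt(abs(est0$theta_deg), 0.05)

  inj <- list(dx_um = 30, dy_um = -17.5, theta_deg = 0)
  mem1 <- render_membrane(tr, g, "t0", transform = inj, seed = 8)
  est1 <- estimate_alignment(mem1, g)
  expect_lt(abs(est1$dx_um - 30), 1.25)   # 0.5 px at 2.5 um/px
  expect_lt(abs(est1$dy_um + 17.5), 1.25)
  expect_false(est1$low_confidence)
})

test_that("rotation is recovered within 0.05 degrees given enough spots", {
  g <- test_geom(21, tile = c(1, 1)) # 441 spots
  tr <- reg_truth(g, seed = 55)
  inj <- list(dx_um = 5, dy_um = 3, theta_deg = 0.5)
  mem <- render_membrane(tr, g, "t0", transform = inj, seed = 9)
  est <- estimate_alignment(mem, g)
  expect_lt(abs(est$theta_deg - 0.5), 0.05)
  expect_lt(abs(est$dx_um - 5), 1.25)
})

test_that("too few spots is an explicit insufficient-signal error", {
  g <- test_geom(8, tile = c(1, 1))
  set.seed(1)
  blank <- fw_mosaic(matrix(500 + round(rnorm(320^2, sd = 30)), 320, 320), 2.5)
  expect_error(estimate_alignment(blank, g), "insufficient signal",
               class = "fw_signal_error")
})

test_that("ROI assignment is geometric and translation-equivariant", {
  g <- test_geom(6, tile = c(1, 1))
  px <- fw_mosaic(matrix(500, 240, 240), 2.5)
  base <- assign_spots_to_wells(px, NULL, g)
  expect_equal(nrow(base), 36) # every well, spots or not
  wc <- well_centers(g)
  expect_equal(base$x_um, wc$x_um)
  shifted <- assign_spots_to_wells(px, fw_transform(12, -7, 0), g)
  expect_equal(shifted$x_um, base$x_um + 12)
  expect_equal(shifted$y_um, base$y_um - 7)
})

test_that("assigned ROIs contain the truth spot positions", {
  g <- test_geom(16, tile = c(1, 1))
  tr <- reg_truth(g, seed = 77)
  inj <- list(dx_um = -22, dy_um = 14, theta_deg = 0.2)
  mem <- render_membrane(tr, g, "t0", transform = inj, seed = 10)
  est <- estimate_alignment(mem, g)
  rois <- assign_spots_to_wells(mem, est, g)
  wc <- well_centers(g)
  truth_pos <- fluorowell:::transform_points(inj, wc$x_um, wc$y_um, g)
  d <- sqrt((rois$x_um - truth_pos$x)^2 + (rois$y_um - truth_pos$y)^2)
  expect_gte(mean(d <= g$spot_roi_radius_um), 0.99)
})
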