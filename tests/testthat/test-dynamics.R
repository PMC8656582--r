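mk_series <- function(rates, above = TRUE, alive = TRUE) {
  tibble::tibble(well_id = 0L, n_cells = 1L,
                 rate_t0 = rates[1], rate_t1 = rates[2], rate_t2 = rates[3],
                 above_bg_t0 = above, above_bg_t1 = above,
                 above_bg_t2 = above,
                 alive_t0 = alive, alive_t1 = alive, alive_t2 = alive,
                 drug_arm = "enzalutamide")
}

test_that("response classification follows the fold/drop rule", {
  expect_equal(classify_response(mk_series(c(2, 8, 1)))$response, "sensitive")
  expect_equal(classify_response(mk_series(c(1, 1.2, 1.1)))$response,
               "insensitive_low")
  expect_equal(classify_response(mk_series(c(2, 8, 9)))$response, "resistant")
  expect_equal(classify_response(mk_series(c(2, 8, 1), alive = FALSE))$response,
               "nonviable")
  # below background at t0 and t1 -> insensitive_low regardless of folds
  s <- mk_series(c(0.01, 0.05, 0.01))
  s$above_bg_t0 <- FALSE; s$above_bg_t1 <- FALSE
  expect_equal(classify_response(s)$response, "insensitive_low")
})

test_that("classification is scale-invariant", {
  set.seed(12)
  for (i in 1:50) {
    r <- runif(3, 0.1, 10)
    c_ <- runif(1, 0.01, 100)
    a <- classify_response(mk_series(r))$response
    b <- classify_response(mk_series(r * c_))$response
    expect_identical(a, b)
  }
})

test_that("time-series assembly respects the well universe and row order", {
  obs <- tibble::tibble(well_id = c(3L, 1L, 2L, 0L),
                        n_cells_detected = c(1L, 0L, 2L, 1L))
  q <- tibble::tibble(well_id = 0:3, mass_pg = c(5, 0, 8, 2),
                      rate_pg_per_cell_day = c(5, NA, 4, 2),
                      above_background = c(TRUE, FALSE, TRUE, TRUE))
  v <- tibble::tibble(well_id = 0:3, n_live = c(1L, 0L, 2L, 0L))
  ser <- build_timeseries(list(t0 = q), list(t0 = v), obs)
  expect_equal(sort(ser$well_id), c(0L, 2L, 3L)) # occupied wells only
  expect_equal(ser$rate_t0[ser$well_id == 2], 4)
  expect_true(is.na(ser$rate_t1[1])) # missing phase flagged, not imputed
  expect_false(ser$alive_t0[ser$well_id == 3])
  # permuting input rows leaves the output invariant
  ser2 <- build_timeseries(list(t0 = q[4:1, ]), list(t0 = v[c(2, 4, 1, 3), ]),
                           obs[c(3, 1, 4, 2), ])
  expect_equal(dplyr::arrange(ser, well_id), dplyr::arrange(ser2, well_id))
  # mismatched universes are a contract error
  expect_error(build_timeseries(list(t0 = q[1:2, ]), list(t0 = v), obs),
               class = "fw_contract_error")
})

test_that("cohort metrics recover the preset stimulation and phenotypes", {
  # series built from truth rates directly: measurement-free oracle
  big <- tibble::tibble(well_id = seq_len(8000) - 1L, cell = 1L,
                        x_um = 0, y_um = 0)
  m <- fw_preset("lncap-timecourse")
  tr <- apply_viability(assign_rates(big, m, seed = 3), m, seed = 4)
  ser <- tibble::tibble(well_id = tr$well_id, n_cells = 1L,
                        rate_t0 = tr$rate_t0, rate_t1 = tr$rate_t1,
                        rate_t2 = tr$rate_t2,
                        above_bg_t0 = tr$secretor & tr$alive_t0,
                        above_bg_t1 = (tr$secretor |
                                         tr$rate_t1 > 0.01) & tr$alive_t1,
                        above_bg_t2 = tr$rate_t2 > 0.01,
                        alive_t0 = tr$alive_t0, alive_t1 = tr$alive_t1,
                        alive_t2 = tr$alive_t2, drug_arm = "enzalutamide")
  cm <- cohort_metrics(ser)
  expect_lt(abs(cm$pct_change_t0_t1 - 91.5), 3)
  # secreting fraction at t0 among viable cells ~ preset 0.53
  sf <- cm$per_phase$secreting_frac[cm$per_phase$phase == "t0"]
  expect_lt(abs(sf - 0.53), 0.03)
  # phenotype fractions among viable secretors within 3 sigma multinomial
  cls <- classify_response(ser)
  viable_sec <- cls$alive_t2 & cls$above_bg_t0
  frac <- table(factor(cls$response[viable_sec],
                       levels = c("sensitive", "insensitive_low",
                                  "resistant")))
  n <- sum(viable_sec)
  probs <- c(0.91, 0.085, 0.005) # conditional on secreting
  for (k in 1:3) {
    expect_lt(abs(frac[k] / n - probs[k]), 3 * sqrt(probs[k] *
                                                      (1 - probs[k]) / n))
  }
  # noise-free recovery: every viable secretor's truth phenotype is returned
  agree <- cls$response[viable_sec] == tr$phenotype[viable_sec] |
    !tr$secretor[viable_sec]
  expect_true(all(agree))
})

test_that("degenerate cohorts behave", {
  s <- mk_series(c(2, 8, 1))
  ser <- dplyr::bind_rows(s, s, s)
  cm <- cohort_metrics(ser)
  expect_equal(cm$per_phase$sd_rate_secretors, rep(0, 3))
  expect_true(all(cm$per_phase$secreting_frac %in% c(0, 1)))
  expect_error(cohort_metrics(s[0, ]), class = "fw_degenerate_error")
  # phenotype + nonviable + unclassified fractions sum to 1
  expect_equal(sum(cm$phenotype_fractions$fraction), 1)
})
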