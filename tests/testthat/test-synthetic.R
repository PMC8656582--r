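test_that("seed_cells honours the occupancy distribution", {
  g <- test_geom(10)
  # degenerate distribution: every well exactly one cell
  t1 <- seed_cells(g, c(0, 1, 0, 0), seed = 3)
  expect_equal(nrow(t1), 100)
  expect_equal(truth_wells(t1, g)$n_cells, rep(1L, 100))
  # offsets stay within the jitter disc
  wc <- well_centers(g)
  m <- match(t1$well_id, wc$well_id)
  expect_true(all(sqrt((t1$x_um - wc$x_um[m])^2 +
                         (t1$y_um - wc$y_um[m])^2) < g$pitch_um / 4))
  expect_error(seed_cells(g, c(0.5, 0.6, 0, 0)), class = "fw_config_error")
})

test_that("default occupancy reproduces the assay's single-cell fraction", {
  g <- chip_geometry()
  tr <- seed_cells(g, population_model()$occupancy_probs, seed = 11)
  frac1 <- mean(truth_wells(tr, g)$n_cells == 1L)
  expect_lt(abs(frac1 * 100 - 92), 2)
})

test_that("occupancy histogram matches multinomial expectation across seeds", {
  g <- test_geom(10)
  probs <- population_model()$occupancy_probs
  counts <- rep(0, 4)
  n_seeds <- 20
  for (s in 1:n_seeds) {
    tw <- truth_wells(seed_cells(g, probs, seed = 100 + s), g)
    counts <- counts + tabulate(tw$n_cells + 1L, nbins = 4)
  }
  n <- 100 * n_seeds
  # exact multinomial SD per category as the oracle tolerance
  sds <- sqrt(n * probs * (1 - probs))
  expect_true(all(abs(counts - n * probs) <= 3 * sds))
})

test_that("assign_rates implements the mixture and lognormal moments", {
  big <- tibble::tibble(well_id = seq_len(1e5) - 1L, cell = 1L,
                        x_um = 0, y_um = 0)
  m <- population_model(secreting_fraction_t0 = 1, basal_rate_mean_pg_day = 6.1,
                        basal_rate_cv = 0.74)
  tr <- assign_rates(big, m, seed = 5)
  # closed-form lognormal moments from (mean, CV) as the oracle
  expect_lt(abs(mean(tr$rate_t0) - 6.1) / 6.1, 0.02)
  expect_lt(abs(sd(tr$rate_t0) / mean(tr$rate_t0) - 0.74) / 0.74, 0.02)

  # CV 0 collapses to a point mass
  tr0 <- assign_rates(big[1:100, ], population_model(basal_rate_cv = 0,
                                                     secreting_fraction_t0 = 1),
                      seed = 6)
  expect_equal(unique(tr0$rate_t0), 6.1)

  # stimulation arithmetic: responsive fraction 0.915 at fold 2 -> ~91.5% mean
  # per-cell increase; insensitive cells unchanged
  inc <- 100 * (tr$rate_t1 - tr$rate_t0) / tr$rate_t0
  expect_lt(abs(mean(inc) - 91.5), 1.5)
  unchanged <- tr$phenotype == "insensitive_low"
  expect_equal(tr$rate_t1[unchanged], tr$rate_t0[unchanged])
  # inhibition applies to sensitive cells only
  sens <- tr$phenotype == "sensitive"
  expect_equal(tr$rate_t2[sens], tr$rate_t1[sens] * m$inhibition_factor)
  expect_equal(tr$rate_t2[!sens], tr$rate_t1[!sens])
})

test_that("occupancy-dependent rate means drive the paired preset", {
  g <- test_geom(16)
  m <- fw_preset("lncap-paired")
  tr <- assign_rates(seed_cells(g, m$occupancy_probs, seed = 9), m, seed = 10)
  wc <- table(tr$well_id)
  tr$wn <- as.integer(wc[as.character(tr$well_id)])
  m1 <- mean(tr$rate_t0[tr$wn == 1 & tr$secretor])
  m2 <- mean(tr$rate_t0[tr$wn == 2 & tr$secretor])
  expect_lt(abs(m1 - 4.8) / 4.8, 0.15)
  expect_lt(abs(m2 - 7.5) / 7.5, 0.15)
})

test_that("viability chain uses marginal fractions and kills secretion", {
  big <- tibble::tibble(well_id = seq_len(6400) - 1L, cell = 1L,
                        x_um = 0, y_um = 0)
  m <- fw_preset("lncap-timecourse", drug_arm = "enzalutamide")
  tr <- apply_viability(assign_rates(big, m, seed = 2), m, seed = 3)
  # all-alive degenerate case
  m_all <- population_model(viability = c(t0 = 1, t1 = 1, t2 = 1))
  tr_all <- apply_viability(assign_rates(big[1:50, ], m_all, seed = 1),
                            m_all, seed = 1)
  expect_true(all(tr_all$alive_t2))

  # realized t2 viable fraction within 3 sigma binomial of 24%
  p <- 0.24; n <- nrow(tr)
  expect_lt(abs(mean(tr$alive_t2) - p), 3 * sqrt(p * (1 - p) / n))
  # chain rule: conditional survival t1 -> t2 is 0.24/0.78
  cond <- mean(tr$alive_t2[tr$alive_t1])
  pc <- 0.24 / 0.78
  expect_lt(abs(cond - pc), 3 * sqrt(pc * (1 - pc) / sum(tr$alive_t1)))
  # alive flags monotone, dead cells secrete 0
  expect_true(all(tr$alive_t1 <= tr$alive_t0 & tr$alive_t2 <= tr$alive_t1))
  expect_true(all(tr$rate_t1[!tr$alive_t1] == 0))
  expect_error(population_model(viability = c(t0 = 0.5, t1 = 0.9, t2 = 0.2)),
               class = "fw_config_error")
})

test_that("simulation stages are deterministic given the seed", {
  g <- test_geom(6)
  m <- population_model()
  a <- assign_rates(seed_cells(g, m$occupancy_probs, 7), m, 8)
  b <- assign_rates(seed_cells(g, m$occupancy_probs, 7), m, 8)
  expect_identical(a, b)
  expect_false(identical(a, assign_rates(seed_cells(g, m$occupancy_probs, 7),
                                         m, 9)))
})
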