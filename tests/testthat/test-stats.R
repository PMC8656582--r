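# brute-force oracle: exact two-sided signed-rank p by enumerating all 2^n
# sign assignments (midranks for ties)
wsr_bruteforce <- function(a, b) {
  d <- (b - a); d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs); p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

test_that("exact signed-rank test matches full enumeration", {
  a <- c(10, 12, 9, 11, 14, 8)
  res <- wilcoxon_signed_rank(a, a + 3)
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 0.03125)
  expect_equal(res$method, "wilcoxon_signed_rank_exact")
  expect_equal(res$stars, "*")

  set.seed(33)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- x + sample(c(-1, 0, 1, 2) / 2, n, replace = TRUE) # forces ties
    if (all(y == x)) y[1] <- x[1] + 1
    if (sum(y != x) < 5) next
    expect_equal(wilcoxon_signed_rank(x, y)$p_value, wsr_bruteforce(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tie-free exact p agrees with the reference implementation", {
  set.seed(9)
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12, 0.5)
    ours <- wilcoxon_signed_rank(x, y)
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("signed-rank degenerate and symmetry properties hold", {
  a <- 1:6
  expect_error(wilcoxon_signed_rank(a, a), class = "fw_degenerate_error")
  expect_error(wilcoxon_signed_rank(1:4, 2:5), class = "fw_contract_error")
  x <- c(1, 3, 2, 5, 4, 7, 6.5)
  y <- x + c(1, -2, 3, 1, -1, 2, 0.5)
  f <- wilcoxon_signed_rank(x, y); r <- wilcoxon_signed_rank(y, x)
  expect_equal(f$p_value, r$p_value)
  n <- f$n
  expect_equal(f$statistic - n * (n + 1) / 4,
               -(r$statistic - n * (n + 1) / 4))
})

test_that("large-sample signed-rank uses the tie-corrected normal tail", {
  set.seed(5)
  x <- rnorm(60); y <- x + rnorm(60, 0.3)
  ours <- wilcoxon_signed_rank(x, y)
  expect_equal(ours$method, "wilcoxon_signed_rank_normal")
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("Welch t matches the closed form and is affine-invariant", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.02131164, tolerance = 1e-6)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(welch_t(3 * a + 2, 3 * b + 2)$p_value, welch_t(a, b)$p_value)
  expect_error(welch_t(rep(1, 3), rep(1, 4)), class = "fw_degenerate_error")
})

test_that("summary statistics follow the boxplot convention", {
  s <- summary_stats(c(1, 2, 3, 4, 5))
  expect_equal(c(s$median, s$q1, s$q3, s$mean), c(3, 2, 4, 3))
  s1 <- summary_stats(7)
  expect_equal(c(s1$mean, s1$median, s1$q1, s1$q3, s1$sd), c(7, 7, 7, 7, 0))
  expect_false(s1$sd_defined)
  # sort-and-interpolate oracle for quartiles
  set.seed(2)
  v <- rnorm(37)
  sv <- sort(v)
  interp <- function(p) {
    h <- (length(sv) - 1) * p
    sv[floor(h) + 1] + (h - floor(h)) * (sv[floor(h) + 2 - (h %% 1 == 0)] -
                                           sv[floor(h) + 1])
  }
  s <- summary_stats(v)
  expect_equal(s$q1, interp(0.25))
  expect_equal(s$q3, interp(0.75))
})

test_that("significance stars map the assay's thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 5e-4, 5e-5)),
               c("ns", "*", "**", "***"))
})
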