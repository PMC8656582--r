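# The assay's statistics: paired Wilcoxon signed-rank with an exact
# tie-corrected null, Welch's t for viability, boxplot-convention summaries,
# and the significance-star mapping.

#' Significance stars
#'
#' The assay's convention: `*` for p < 0.05, `**` for p < 0.001, `***` for
#' p < 0.0001, `"ns"` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p < 1e-4 ~ "***", p < 1e-3 ~ "**", p < 0.05 ~ "*",
                   TRUE ~ "ns")
}

new_fw_test <- function(statistic, p_value, n, method, ...) {
  structure(list(statistic = statistic, p_value = p_value, n = n,
                 method = method, stars = significance_stars(p_value), ...),
            class = "fw_test")
}

#' @export
print.fw_test <- function(x, ...) {
  cat(sprintf("<fw_test> %s: statistic = %.4g, n = %d, p = %.4g %s\n",
              x$method, x$statistic, x$n, x$p_value, x$stars))
  invisible(x)
}

# Exact null distribution of the (doubled) signed-rank statistic via the
# generating-function DP over midranks: identical to enumerating all 2^n sign
# assignments, but polynomial-time. Returns P(W2 = 0..sum(w2)).
signed_rank_null <- function(w2) {
  tot <- sum(w2)
  pmf <- numeric(tot + 1); pmf[1] <- 1
  for (w in w2) {
    shifted <- c(rep(0, w), pmf[seq_len(tot + 1 - w)])
    pmf <- (pmf + shifted) / 2
  }
  pmf
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Zero differences are
#' discarded (the classical treatment); tied absolute differences receive
#' midranks. For n <= `exact_max` pairs the null distribution is computed
#' exactly (equivalent to enumerating every sign assignment, with ties
#' honoured); beyond that, the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param a,b paired measurement vectors of equal length.
#' @param exact_max largest n for which the exact null is used.
#' @return An `fw_test` with `statistic` (W = sum of ranks of positive
#'   differences b - a), `p_value`, `n` (non-zero pairs), `method`, `stars`.
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25) {
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) {
    fw_stop("all paired differences are zero: signed-rank test undefined",
            class = "fw_degenerate_error")
  }
  n <- length(d)
  if (n < 5) {
    fw_stop("need >= 5 non-zero paired differences (got ", n, ")",
            class = "fw_contract_error")
  }
  r <- rank(abs(d)) # midranks for ties
  w_obs <- sum(r[d > 0])
  if (n <= exact_max) {
    w2 <- as.integer(round(2 * r))
    pmf <- signed_rank_null(w2)
    obs2 <- as.integer(round(2 * w_obs))
    p_lo <- sum(pmf[seq_len(obs2 + 1)])
    p_hi <- sum(pmf[(obs2 + 1):length(pmf)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "wilcoxon_signed_rank_exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_obs - mu - 0.5 * sign(w_obs - mu)) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "wilcoxon_signed_rank_normal"
  }
  new_fw_test(w_obs, p, n, method)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test (Satterthwaite degrees of freedom), two-sided, as
#' used for cohort viability comparisons. Wraps [stats::t.test()].
#'
#' @param x,y samples (each n >= 2).
#' @return An `fw_test` with `statistic` (t), `df`, `p_value`, `n`
#'   (total observations), `stars`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    fw_stop("each sample needs n >= 2", class = "fw_contract_error")
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    fw_stop("both samples have zero variance: t-test degenerate",
            class = "fw_degenerate_error")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  out <- new_fw_test(unname(ht$statistic), ht$p.value,
                     length(x) + length(y), "welch_t")
  out$df <- unname(ht$parameter)
  out
}

#' Boxplot-convention summary statistics
#'
#' Mean, sample SD (n - 1 denominator), and quartiles by linear interpolation
#' between order statistics (`stats::quantile()` type 7): the bottom and top
#' of the box are q1 and q3, the band is the median, the square marks the
#' mean. A single value yields SD 0 with `sd_defined = FALSE`.
#'
#' @param values numeric vector (n >= 1).
#' @return One-row tibble: `n`, `mean`, `sd`, `median`, `q1`, `q3`,
#'   `sd_defined`.
#' @export
summary_stats <- function(values) {
  values <- values[!is.na(values)]
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(n = length(values), mean = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0,
                 median = q[2], q1 = q[1], q3 = q[3],
                 sd_defined = length(values) > 1)
}
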