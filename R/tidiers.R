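# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted calibration curve
#'
#' @param x an [fit_calibration()] result.
#' @param ... unused.
#' @return Tibble with one row per parameter (`i_bg`, `i_max`, `rho_half`).
#' @export
tidy.fw_calibration <- function(x, ...) {
  tibble::tibble(term = c("i_bg", "i_max", "rho_half"),
                 estimate = c(x$i_bg, x$i_max, x$rho_half))
}

#' @rdname tidy.fw_calibration
#' @return `glance()`: one-row tibble with fit RMS residual `sigma`,
#'   `n_standards`, and the valid density range.
#' @export
glance.fw_calibration <- function(x, ...) {
  tibble::tibble(sigma = x$sigma, n_standards = nrow(x$standards),
                 rho_max = x$rho_max)
}

#' Tidy a test result
#'
#' @param x an `fw_test` (from [wilcoxon_signed_rank()] or [welch_t()]).
#' @param ... unused.
#' @return One-row tibble: `method`, `statistic`, `p.value`, `n`, `stars`.
#' @export
tidy.fw_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p.value = x$p_value, n = x$n, stars = x$stars)
}

#' Tidy an estimated rigid alignment
#'
#' @param x an [fw_transform()].
#' @param ... unused.
#' @return One-row tibble: `dx_um`, `dy_um`, `theta_deg`, `residual_um`,
#'   `n_inliers`, `low_confidence`.
#' @export
tidy.fw_transform <- function(x, ...) {
  tibble::tibble(dx_um = x$dx_um, dy_um = x$dy_um, theta_deg = x$theta_deg,
                 residual_um = x$residual_um, n_inliers = x$n_inliers,
                 low_confidence = x$low_confidence)
}

#' Tidy a cohort summary
#'
#' @param x an `fw_cohort` from [cohort_metrics()].
#' @param ... unused.
#' @return The per-phase tibble (viable fraction, secreting fraction, rate
#'   mean/SD among secretors).
#' @export
tidy.fw_cohort <- function(x, ...) {
  x$per_phase
}

#' @rdname tidy.fw_cohort
#' @return `glance()`: one-row tibble with `n_wells`, `pct_change_t0_t1`,
#'   `n_change`.
#' @export
glance.fw_cohort <- function(x, ...) {
  tibble::tibble(n_wells = x$n_wells, pct_change_t0_t1 = x$pct_change_t0_t1,
                 n_change = x$n_change)
}
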