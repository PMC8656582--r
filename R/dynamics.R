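# Per-well secretion time series across the three membranes and
# drug-response phenotype classification.

#' Assemble per-well secretion time series
#'
#' Joins the quantified membranes and viability observations of the three
#' phases into one wide series per occupied well. Missing phases are flagged
#' (`NA` rates), never imputed.
#'
#' @param quantified named list of [quantify_spots()] tables for phases
#'   `t0`, `t1`, `t2` (a phase may be `NULL`).
#' @param viability named list of [viability_per_well()] tables per phase.
#' @param loading_obs loading-image [count_cells_per_well()] table; wells with
#'   at least one detected cell define the series universe.
#' @param drug_arm label carried into the output (`"enzalutamide"`,
#'   `"abiraterone"`, or `NA`).
#' @return Tibble with one row per occupied well: `well_id`, `n_cells`,
#'   `rate_t*` (pg/cell/day), `above_bg_t*`, `alive_t*`, `drug_arm`.
#' @export
build_timeseries <- function(quantified, viability, loading_obs,
                             drug_arm = NA_character_) {
  occ <- loading_obs[loading_obs$n_cells_detected >= 1L, ]
  out <- tibble::tibble(well_id = occ$well_id,
                        n_cells = occ$n_cells_detected)
  for (ph in c("t0", "t1", "t2")) {
    q <- quantified[[ph]]
    if (!is.null(q)) {
      if (!all(out$well_id %in% q$well_id)) {
        fw_stop("phase ", ph, " quantification covers a different well ",
                "universe than the loading observations",
                class = "fw_contract_error")
      }
      m <- match(out$well_id, q$well_id)
      out[[paste0("rate_", ph)]] <- q$rate_pg_per_cell_day[m]
      out[[paste0("above_bg_", ph)]] <- q$above_background[m]
    } else {
      out[[paste0("rate_", ph)]] <- NA_real_
      out[[paste0("above_bg_", ph)]] <- NA
    }
    v <- viability[[ph]]
    if (!is.null(v)) {
      m <- match(out$well_id, v$well_id)
      out[[paste0("alive_", ph)]] <- v$n_live[m] >= 1L
    } else {
      out[[paste0("alive_", ph)]] <- NA
    }
  }
  out$drug_arm <- drug_arm
  out
}

#' Classify the drug-response phenotype of each series
#'
#' Rule (exhaustive, mutually exclusive):
#' * `nonviable` — not alive at t2;
#' * `insensitive_low` — t0 and t1 both below background, or stimulation fold
#'   t1/t0 below `stim_fold_min`;
#' * `sensitive` — fold >= `stim_fold_min` and inhibition drop
#'   1 - t2/t1 >= `drop_min`;
#' * `resistant` — fold >= `stim_fold_min` but drop < `drop_min`;
#' * `unclassified` — anything else (missing phases etc.).
#'
#' Classification is scale-invariant: rescaling all three rates of a series
#' leaves the label unchanged (above-background flags held fixed).
#'
#' @param series output of [build_timeseries()].
#' @param stim_fold_min minimum t1/t0 fold to call a cell stimulated.
#' @param drop_min minimum fractional drop t1 -> t2 to call it inhibited.
#' @return `series` with added `fold_stim`, `drop_inhib`, `response` columns.
#' @export
classify_response <- function(series, stim_fold_min = 1.5, drop_min = 0.30) {
  fold <- series$rate_t1 / series$rate_t0
  drop <- 1 - series$rate_t2 / series$rate_t1
  lab <- rep("unclassified", nrow(series))
  below01 <- !series$above_bg_t0 & !series$above_bg_t1
  fold_cmp <- ifelse(is.nan(fold), 0, fold) # 0/0: never stimulated
  lab[!is.na(below01) & below01] <- "insensitive_low"
  lab[!is.na(fold_cmp) & fold_cmp < stim_fold_min & !(!is.na(below01) & below01)] <-
    "insensitive_low"
  stim <- !is.na(fold_cmp) & fold_cmp >= stim_fold_min &
    !(!is.na(below01) & below01)
  drop_cmp <- ifelse(is.nan(drop), 0, drop)
  lab[stim & !is.na(drop_cmp) & drop_cmp >= drop_min] <- "sensitive"
  lab[stim & !is.na(drop_cmp) & drop_cmp < drop_min] <- "resistant"
  lab[is.na(series$alive_t2) | !series$alive_t2] <- "nonviable"
  dplyr::mutate(series, fold_stim = fold, drop_inhib = drop, response = lab)
}

#' Cohort summary of a set of secretion time series
#'
#' Per phase: viable fraction, secreting fraction (viable and above
#' background), and mean/SD rate among secretors. Across phases: mean
#' per-cell percent change t0 -> t1 over wells viable at both phases and
#' above background at t0, and the response-phenotype fractions.
#'
#' @param series output of [build_timeseries()] (classified or not).
#' @param stim_fold_min,drop_min thresholds forwarded to
#'   [classify_response()] when `series` has no `response` column.
#' @return List of class `fw_cohort`: `per_phase` tibble,
#'   `pct_change_t0_t1`, `n_change`, `phenotype_fractions` tibble, `n_wells`.
#' @export
cohort_metrics <- function(series, stim_fold_min = 1.5, drop_min = 0.30) {
  if (nrow(series) == 0) {
    fw_stop("empty cohort", class = "fw_degenerate_error")
  }
  if (!"response" %in% names(series)) {
    series <- classify_response(series, stim_fold_min, drop_min)
  }
  per_phase <- purrr::map_dfr(c("t0", "t1", "t2"), function(ph) {
    alive <- series[[paste0("alive_", ph)]]
    ab <- series[[paste0("above_bg_", ph)]]
    rate <- series[[paste0("rate_", ph)]]
    sec <- !is.na(alive) & alive & !is.na(ab) & ab
    tibble::tibble(
      phase = ph,
      viable_frac = mean(alive, na.rm = TRUE),
      secreting_frac = sum(sec) / max(sum(!is.na(alive) & alive), 1L),
      mean_rate_secretors = if (any(sec)) mean(rate[sec]) else NA_real_,
      sd_rate_secretors = if (sum(sec) > 1) stats::sd(rate[sec]) else NA_real_)
  })
  chg_sel <- !is.na(series$alive_t0) & series$alive_t0 &
    !is.na(series$alive_t1) & series$alive_t1 &
    !is.na(series$above_bg_t0) & series$above_bg_t0 &
    !is.na(series$rate_t0) & series$rate_t0 > 0
  pct <- 100 * (series$rate_t1[chg_sel] - series$rate_t0[chg_sel]) /
    series$rate_t0[chg_sel]
  phen <- dplyr::count(series, .data$response)
  phen$fraction <- phen$n / sum(phen$n)
  structure(list(per_phase = per_phase,
                 pct_change_t0_t1 = if (length(pct)) mean(pct) else NA_real_,
                 n_change = length(pct),
                 phenotype_fractions = phen,
                 n_wells = nrow(series)),
            class = "fw_cohort")
}

#' @export
print.fw_cohort <- function(x, ...) {
  cat("<fw_cohort>", x$n_wells, "wells\n")
  print(x$per_phase)
  cat(sprintf("mean %% change t0->t1 (viable secretors, n=%d): %.1f%%\n",
              x$n_change, x$pct_change_t0_t1))
  print(x$phenotype_fractions)
  invisible(x)
}
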