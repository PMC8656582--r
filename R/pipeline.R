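# End-to-end analysis of a simulated (or equivalently structured) run
# directory, and the one-call simulate-and-analyze pipeline.

#' Analyze a run directory end to end
#'
#' Recovers everything from the images alone: counts cells on the loading
#' image, measures per-phase viability from the live/dead pairs, fits the
#' calibration curve from the standards membrane, registers each capture
#' membrane into the chip frame, quantifies every well against the curve with
#' empty-well background statistics, assembles per-well time series, and
#' classifies drug-response phenotypes. The injected simulator offsets in the
#' manifest are never read.
#'
#' Stage outputs are written into `run_dir`: `wells_loading.csv`,
#' `wells_{phase}.csv`, `alignment_{phase}.yaml`, `secretion_{phase}.csv`,
#' `calibration.yaml`, `timeseries.csv`, `cohort_summary.yaml`, `stats.yaml`
#' and `report.md`.
#'
#' @param run_dir directory produced by [simulate_experiment()].
#' @param detect_params an [fw_detect_params()].
#' @param min_bg_wells minimum empty wells for the background rule.
#' @param min_spots minimum detected spots required for registration.
#' @param k_bg above-background SD multiplier.
#' @param stim_fold_min,drop_min classification thresholds.
#' @param write_outputs write stage CSV/YAML files (default TRUE).
#' @return List of class `fw_run`: `loading` counts, `viability` per phase,
#'   `calibration`, `background`, `alignments`, `quantified` per phase,
#'   `series` (classified), `cohort`, `duration_h`.
#' @export
analyze_experiment <- function(run_dir, detect_params = fw_detect_params(),
                               min_bg_wells = 50, min_spots = 50, k_bg = 3,
                               stim_fold_min = 1.5, drop_min = 0.30,
                               write_outputs = TRUE) {
  manifest_path <- file.path(run_dir, "manifest.yaml")
  man <- read_manifest(manifest_path)
  geometry <- geometry_from_list(man$geometry)
  phase_names <- setdiff(vapply(man$phases, `[[`, "", "name"), "loading")
  duration_h <- man$phases[[length(man$phases)]]$duration_h %||% 24

  loading <- count_cells_per_well(read_tile_grid(manifest_path, "loading",
                                                 "cell"),
                                  geometry, detect_params)
  if (write_outputs) {
    utils::write.csv(loading, file.path(run_dir, "wells_loading.csv"),
                     row.names = FALSE)
  }

  has <- function(ph, ch) {
    any(vapply(man$tiles, function(t) identical(t$phase, ph) &&
                 identical(t$channel, ch), logical(1)))
  }

  viability <- list(); alignments <- list(); quantified <- list()
  curve <- NULL; background <- NULL
  if (has("calibration", "membrane")) {
    cal_truth <- utils::read.csv(file.path(run_dir, "truth_calibration.csv"))
    cal_mosaic <- read_tile_grid(manifest_path, "calibration", "membrane")
    curve <- fit_calibration(measure_calibration_spots(cal_mosaic, cal_truth))
    if (write_outputs) {
      yaml::write_yaml(list(i_bg = curve$i_bg, i_max = curve$i_max,
                            rho_half = curve$rho_half,
                            rho_max = curve$rho_max, sigma = curve$sigma,
                            standards = as.list(curve$standards$density)),
                       file.path(run_dir, "calibration.yaml"))
    }
  }

  for (ph in phase_names) {
    if (has(ph, "cell") && has(ph, "dead")) {
      viability[[ph]] <- viability_per_well(
        read_tile_grid(manifest_path, ph, "cell"),
        read_tile_grid(manifest_path, ph, "dead"), geometry, detect_params)
      if (write_outputs) {
        utils::write.csv(viability[[ph]],
                         file.path(run_dir, sprintf("wells_%s.csv", ph)),
                         row.names = FALSE)
      }
    }
    if (has(ph, "membrane") && !is.null(curve)) {
      mem <- read_tile_grid(manifest_path, ph, "membrane")
      tr <- estimate_alignment(mem, geometry, min_spots = min_spots)
      alignments[[ph]] <- tr
      spots <- assign_spots_to_wells(mem, tr, geometry)
      if (is.null(background)) {
        background <- estimate_background(spots, loading,
                                          min_wells = min_bg_wells)
      }
      quantified[[ph]] <- quantify_spots(spots, curve, background, loading,
                                         duration_h = duration_h, k_bg = k_bg)
      if (write_outputs) {
        yaml::write_yaml(list(dx_um = tr$dx_um, dy_um = tr$dy_um,
                              theta_deg = tr$theta_deg,
                              residual_um = tr$residual_um,
                              n_inliers = tr$n_inliers,
                              low_confidence = tr$low_confidence),
                         file.path(run_dir, sprintf("alignment_%s.yaml", ph)))
        utils::write.csv(quantified[[ph]],
                         file.path(run_dir, sprintf("secretion_%s.csv", ph)),
                         row.names = FALSE)
      }
    }
  }

  series <- NULL; cohort <- NULL
  if (length(quantified) > 0 || length(viability) > 0) {
    series <- build_timeseries(quantified, viability, loading,
                               drug_arm = man$drug_arm %||% NA_character_)
    series <- classify_response(series, stim_fold_min, drop_min)
    cohort <- cohort_metrics(series)
    if (write_outputs) {
      utils::write.csv(series, file.path(run_dir, "timeseries.csv"),
                       row.names = FALSE)
      yaml::write_yaml(cohort_to_list(cohort),
                       file.path(run_dir, "cohort_summary.yaml"))
    }
  }

  out <- structure(list(run_dir = run_dir, loading = loading,
                        viability = viability, calibration = curve,
                        background = background, alignments = alignments,
                        quantified = quantified, series = series,
                        cohort = cohort, duration_h = duration_h),
                   class = "fw_run")
  if (write_outputs) write_report(out)
  out
}

cohort_to_list <- function(cohort) {
  list(n_wells = cohort$n_wells,
       per_phase = lapply(seq_len(nrow(cohort$per_phase)), function(i)
         as.list(cohort$per_phase[i, ])),
       pct_change_t0_t1 = cohort$pct_change_t0_t1,
       n_change = cohort$n_change,
       phenotype_fractions = lapply(seq_len(nrow(cohort$phenotype_fractions)),
                                    function(i)
                                      as.list(cohort$phenotype_fractions[i, ])))
}

#' Write the cohort report
#'
#' Emits `report.md` (human-readable tables: occupancy, per-phase viability
#' and secretion summaries, phenotype fractions, tests) and `stats.yaml`
#' (machine-readable) into the run directory.
#'
#' @param run an `fw_run` from [analyze_experiment()].
#' @return Invisibly, the report path.
#' @export
write_report <- function(run) {
  path <- file.path(run$run_dir, "report.md")
  occ <- table(factor(pmin(run$loading$n_cells_detected, 3), levels = 0:3))
  lines <- c("# Cohort report", "",
             "## Occupancy (detected cells per well)", "",
             sprintf("- %s cells: %d wells (%.1f%%)", names(occ), as.integer(occ),
                     100 * as.integer(occ) / sum(occ)))
  stats_out <- list(occupancy = as.list(stats::setNames(as.integer(occ),
                                                        names(occ))))
  for (ph in names(run$viability)) {
    v <- cohort_viability(run$viability[[ph]])
    lines <- c(lines, "", sprintf("## Viability %s: %.1f%%", ph, v))
    stats_out$viability[[ph]] <- v
  }
  if (!is.null(run$cohort)) {
    pp <- run$cohort$per_phase
    lines <- c(lines, "", "## Secretion per phase", "",
               "| phase | viable | secreting | mean rate (pg/cell/day) | SD |",
               "|---|---|---|---|---|",
               sprintf("| %s | %.2f | %.2f | %.2f | %.2f |", pp$phase,
                       pp$viable_frac, pp$secreting_frac,
                       pp$mean_rate_secretors, pp$sd_rate_secretors),
               "",
               sprintf("Mean per-cell change t0->t1: %+.1f%% (n = %d)",
                       run$cohort$pct_change_t0_t1, run$cohort$n_change),
               "", "## Response phenotypes", "",
               sprintf("- %s: %.1f%%", run$cohort$phenotype_fractions$response,
                       100 * run$cohort$phenotype_fractions$fraction))
    stats_out$cohort <- cohort_to_list(run$cohort)
    # paired t0 vs t1 comparison among viable secretors, the assay's test
    s <- run$series
    sel <- !is.na(s$rate_t0) & !is.na(s$rate_t1) & s$alive_t1 %in% TRUE &
      s$above_bg_t0 %in% TRUE
    if (sum(sel) >= 5) {
      ts <- wilcoxon_signed_rank(s$rate_t0[sel], s$rate_t1[sel])
      lines <- c(lines, "",
                 sprintf("Wilcoxon signed-rank t0 vs t1: W = %.0f, p = %.3g %s",
                         ts$statistic, ts$p_value, ts$stars))
      stats_out$wilcoxon_t0_t1 <- list(statistic = ts$statistic,
                                       p_value = ts$p_value, n = ts$n,
                                       stars = ts$stars)
    }
  }
  writeLines(lines, path)
  yaml::write_yaml(stats_out, file.path(run$run_dir, "stats.yaml"))
  invisible(path)
}

#' @export
print.fw_run <- function(x, ...) {
  cat("<fw_run>", x$run_dir, "\n")
  if (!is.null(x$cohort)) print(x$cohort)
  invisible(x)
}

#' Simulate and analyze in one call
#'
#' Runs [simulate_experiment()] and [analyze_experiment()] under one run
#' directory with one master seed. Identical configuration and seed give
#' identical outputs.
#'
#' @param out_dir run directory.
#' @param ... passed to [simulate_experiment()].
#' @param detect_params,min_bg_wells,min_spots,k_bg,stim_fold_min,drop_min
#'   passed to [analyze_experiment()].
#' @return The `fw_run` from [analyze_experiment()].
#' @export
run_pipeline <- function(out_dir, ..., detect_params = fw_detect_params(),
                         min_bg_wells = 50, min_spots = 50, k_bg = 3,
                         stim_fold_min = 1.5, drop_min = 0.30) {
  simulate_experiment(out_dir, ...)
  analyze_experiment(out_dir, detect_params = detect_params,
                     min_bg_wells = min_bg_wells, min_spots = min_spots,
                     k_bg = k_bg, stim_fold_min = stim_fold_min,
                     drop_min = drop_min)
}
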