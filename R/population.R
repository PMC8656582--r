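#' Population model for the forward simulator
#'
#' Describes the cell population loaded on a chip: how many cells land per
#' well, which fraction secretes detectably at baseline, the lognormal basal
#' secretion-rate distribution, the drug-response phenotype mixture, the
#' multiplicative effect of androgen stimulation and anti-androgen inhibition,
#' and marginal viability at each measurement.
#'
#' Rates are pg of secreted protein per cell per day. `viability` holds the
#' *marginal* viable fraction at the end of each 24 h phase; conditional
#' survival from phase p-1 to p is `viability[p] / viability[p-1]`, so the
#' sequence must be non-increasing. Stimulation multiplies the t1 rate of
#' sensitive and resistant secretors; inhibition multiplies the t2 rate of
#' sensitive cells only; dead cells secrete 0 from the phase of death onward.
#'
#' @param occupancy_probs probabilities of 0/1/2/3 cells per well (renormalised
#'   if slightly off 1, as the assay's printed histogram is).
#' @param secreting_fraction_t0 fraction of cells above background at baseline.
#' @param basal_rate_mean_pg_day,basal_rate_cv mean and coefficient of
#'   variation of the lognormal basal rate of secreting cells.
#' @param phenotype_fractions named fractions `sensitive`, `insensitive_low`,
#'   `resistant`; must sum to 1.
#' @param stimulation_fold multiplier applied at t1 to sensitive and resistant
#'   secretors.
#' @param inhibition_factor multiplier applied at t2 to sensitive cells.
#' @param viability named marginal viable fractions `t0`, `t1`, `t2`.
#' @param nonsecretor_rate_pg_day residual rate of below-background cells.
#' @param rate_mean_by_count optional named list mapping a well's cell count
#'   (as character, e.g. `"2"`) to a basal-rate mean, overriding
#'   `basal_rate_mean_pg_day` for cells in wells of that occupancy. Lets the
#'   paired one- vs two-cell study condition pin both group means.
#' @return An object of class `fw_population`.
#' @export
population_model <- function(occupancy_probs = c(0.02, 0.92, 0.04, 0.03) / 1.01,
                             secreting_fraction_t0 = 0.95,
                             basal_rate_mean_pg_day = 6.1,
                             basal_rate_cv = 4.5 / 6.1,
                             phenotype_fractions = c(sensitive = 0.91,
                                                     insensitive_low = 0.085,
                                                     resistant = 0.005),
                             stimulation_fold = 2.0,
                             inhibition_factor = 0.15,
                             viability = c(t0 = 0.88, t1 = 0.78, t2 = 0.24),
                             nonsecretor_rate_pg_day = 0.001,
                             rate_mean_by_count = NULL) {
  check_probs(occupancy_probs, "occupancy_probs", tol = 1e-9)
  check_probs(phenotype_fractions, "phenotype_fractions")
  stopifnot(secreting_fraction_t0 >= 0, secreting_fraction_t0 <= 1,
            basal_rate_mean_pg_day >= 0, basal_rate_cv >= 0,
            stimulation_fold > 0, inhibition_factor > 0,
            nonsecretor_rate_pg_day >= 0)
  viability <- viability[c("t0", "t1", "t2")]
  if (anyNA(viability) || any(viability < 0) || any(viability > 1)) {
    fw_stop("viability must provide fractions in [0,1] named t0, t1, t2",
            class = "fw_config_error")
  }
  if (any(diff(viability) > 1e-12)) {
    fw_stop("viability sequence must be non-increasing (marginal viable ",
            "fractions; cells do not resurrect)", class = "fw_config_error")
  }
  structure(list(occupancy_probs = occupancy_probs / sum(occupancy_probs),
                 secreting_fraction_t0 = secreting_fraction_t0,
                 basal_rate_mean_pg_day = basal_rate_mean_pg_day,
                 basal_rate_cv = basal_rate_cv,
                 phenotype_fractions = phenotype_fractions,
                 stimulation_fold = stimulation_fold,
                 inhibition_factor = inhibition_factor,
                 viability = viability,
                 nonsecretor_rate_pg_day = nonsecretor_rate_pg_day,
                 rate_mean_by_count = rate_mean_by_count),
            class = "fw_population")
}

#' Built-in population presets
#'
#' Presets pin the simulator to the assay's reported cohort numbers:
#'
#' * `lncap-basal` — LNCaP baseline: 6.1 pg/cell/day mean (SD 4.5), >90% of
#'   single cells secreting.
#' * `vcap-basal` — VCaP baseline: 3.7 pg/cell/day mean (SD 1.9).
#' * `lncap-timecourse` — three-phase LNCaP arm: baseline secreting fraction
#'   0.53, 2-fold androgen stimulation of the responsive 91.5%, sharp
#'   inhibition of sensitive cells; end-of-arm viability 24%
#'   (enzalutamide) or 39% (abiraterone).
#' * `vcap-timecourse` — VCaP arm: baseline secreting fraction 0.30;
#'   viability 29% (enzalutamide) / 46% (abiraterone).
#' * `lncap-paired` — one- vs two-cell comparison: single-cell wells secrete
#'   4.8 pg/cell/day on average, two-cell wells 7.5 pg/cell/day per cell,
#'   with occupancy weighted toward pairs (observed cohort ratio ~3.7:1).
#'
#' @param name preset name (see above).
#' @param drug_arm `"enzalutamide"` or `"abiraterone"`; selects the t2
#'   viability of the time-course presets.
#' @return An `fw_population`.
#' @export
fw_preset <- function(name = c("lncap-basal", "vcap-basal",
                               "lncap-timecourse", "vcap-timecourse",
                               "lncap-paired"),
                      drug_arm = c("enzalutamide", "abiraterone")) {
  name <- match.arg(name)
  drug_arm <- match.arg(drug_arm)
  v2 <- list(
    `lncap-timecourse` = c(enzalutamide = 0.24, abiraterone = 0.39),
    `vcap-timecourse`  = c(enzalutamide = 0.29, abiraterone = 0.46)
  )
  switch(name,
    "lncap-basal" = population_model(),
    "vcap-basal" = population_model(basal_rate_mean_pg_day = 3.7,
                                    basal_rate_cv = 1.9 / 3.7),
    "lncap-timecourse" = population_model(
      secreting_fraction_t0 = 0.53,
      viability = c(t0 = 0.88, t1 = 0.78,
                    t2 = unname(v2[[name]][drug_arm]))),
    "vcap-timecourse" = population_model(
      basal_rate_mean_pg_day = 3.7, basal_rate_cv = 1.9 / 3.7,
      secreting_fraction_t0 = 0.30,
      viability = c(t0 = 0.88, t1 = 0.78,
                    t2 = unname(v2[[name]][drug_arm]))),
    "lncap-paired" = population_model(
      occupancy_probs = c(0.02, 0.74, 0.20, 0.04),
      basal_rate_mean_pg_day = 4.8, basal_rate_cv = 4.5 / 6.1,
      rate_mean_by_count = list(`1` = 4.8, `2` = 7.5))
  )
}
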