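# Ground-truth simulation: occupancy, positions, rates, phenotypes, viability.

# Place n cells inside a well, offsets relative to the well centre (um).
# Single cells land near the pore with uniform-in-disc jitter; pairs/triples
# sit on a ring (randomly rotated) so they stay resolvable at the rendering
# PSF while honouring |offset| < pitch/4.
cell_offsets <- function(n, pitch_um) {
  rmax <- pitch_um / 4
  if (n == 1) {
    r <- (rmax - 2) * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    cbind(r * cos(a), r * sin(a))
  } else {
    ring <- min(c(0, 20, 22)[min(n, 3)], rmax - 3)
    a0 <- stats::runif(1, 0, 2 * pi)
    a <- a0 + 2 * pi * (seq_len(n) - 1) / n
    jit <- matrix(stats::rnorm(2 * n, sd = 1), ncol = 2)
    off <- cbind(ring * cos(a), ring * sin(a)) + jit
    # clamp within the jitter disc
    rr <- sqrt(rowSums(off^2))
    s <- pmin(1, (rmax - 1) / pmax(rr, 1e-9))
    off * s
  }
}

#' Seed cells into wells
#'
#' Draws each well's cell count i.i.d. from `occupancy_probs` and places the
#' cells at jittered positions inside the well (|offset| < pitch/4 from the
#' well centre). Deterministic given the seed.
#'
#' @param geometry a [chip_geometry()].
#' @param occupancy_probs probabilities for 0, 1, 2, 3 cells per well.
#' @param seed integer seed for this stage.
#' @return A truth tibble with one row per cell: `well_id`, `cell` (index
#'   within the well), `x_um`, `y_um`.
#' @export
seed_cells <- function(geometry, occupancy_probs, seed = 1L) {
  check_probs(occupancy_probs, "occupancy_probs", tol = 1e-9)
  centers <- well_centers(geometry)
  old <- .Random.seed_exists()
  set.seed(seed)
  n_cells <- sample(0:3, nrow(centers), replace = TRUE, prob = occupancy_probs)
  rows <- lapply(which(n_cells > 0L), function(i) {
    n <- n_cells[i]
    off <- cell_offsets(n, geometry$pitch_um)
    tibble::tibble(well_id = centers$well_id[i], cell = seq_len(n),
                   x_um = centers$x_um[i] + off[, 1],
                   y_um = centers$y_um[i] + off[, 2])
  })
  .restore_seed(old)
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(well_id = integer(), cell = integer(),
                          x_um = double(), y_um = double())
  }
  out
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Assign secretion rates and drug-response phenotypes
#'
#' Each cell is a secretor with probability `secreting_fraction_t0`; its
#' phenotype is drawn from the model's mixture. Secretors draw a lognormal
#' basal rate (arithmetic mean `basal_rate_mean_pg_day`, CV `basal_rate_cv`);
#' non-secretors get the residual `nonsecretor_rate_pg_day`. At t1 the rate of
#' sensitive and resistant secretors is multiplied by `stimulation_fold`; at
#' t2 the rate of sensitive cells is multiplied by `inhibition_factor`.
#'
#' @param truth output of [seed_cells()].
#' @param model an [population_model()].
#' @param seed integer seed for this stage.
#' @return The truth tibble with added columns `secretor`, `phenotype`,
#'   `rate_t0`, `rate_t1`, `rate_t2` (pg/cell/day).
#' @export
assign_rates <- function(truth, model, seed = 1L) {
  stopifnot(inherits(model, "fw_population"))
  n <- nrow(truth)
  old <- .Random.seed_exists()
  set.seed(seed)
  secretor <- stats::runif(n) < model$secreting_fraction_t0
  phen <- sample(names(model$phenotype_fractions), n, replace = TRUE,
                 prob = model$phenotype_fractions)
  # per-cell basal mean, optionally occupancy-dependent
  mean_vec <- rep(model$basal_rate_mean_pg_day, n)
  if (!is.null(model$rate_mean_by_count) && n > 0) {
    counts <- table(truth$well_id)
    wc <- as.integer(counts[as.character(truth$well_id)])
    for (k in names(model$rate_mean_by_count)) {
      mean_vec[wc == as.integer(k)] <- model$rate_mean_by_count[[k]]
    }
  }
  if (model$basal_rate_cv > 0) {
    z <- stats::rnorm(n)
    sdlog <- sqrt(log1p(model$basal_rate_cv^2))
    rate0 <- exp(log(mean_vec) - sdlog^2 / 2 + sdlog * z)
  } else {
    rate0 <- mean_vec
  }
  .restore_seed(old)
  rate0[!secretor] <- model$nonsecretor_rate_pg_day
  responsive <- secretor & phen %in% c("sensitive", "resistant")
  rate1 <- rate0 * ifelse(responsive, model$stimulation_fold, 1)
  rate2 <- rate1 * ifelse(phen == "sensitive", model$inhibition_factor, 1)
  dplyr::mutate(truth, secretor = secretor, phenotype = phen,
                rate_t0 = rate0, rate_t1 = rate1, rate_t2 = rate2)
}

#' Apply the viability model
#'
#' Survival to each phase is Bernoulli with the model's marginal viable
#' fractions; conditional survival from phase p-1 to p is
#' `viability[p]/viability[p-1]`, so alive flags are monotone non-increasing.
#' Dead cells secrete 0 from the phase of death onward.
#'
#' @param truth output of [assign_rates()].
#' @param model an [population_model()] (its `viability` element is used; for
#'   the drug arms use the preset built for that arm).
#' @param seed integer seed for this stage.
#' @return Truth tibble with `alive_t0`, `alive_t1`, `alive_t2` and rates
#'   zeroed from the phase of death onward.
#' @export
apply_viability <- function(truth, model, seed = 1L) {
  v <- model$viability
  n <- nrow(truth)
  cond <- c(v[1], v[2] / max(v[1], 1e-12), v[3] / max(v[2], 1e-12))
  old <- .Random.seed_exists()
  set.seed(seed)
  a0 <- stats::runif(n) < cond[1]
  a1 <- a0 & (stats::runif(n) < cond[2])
  a2 <- a1 & (stats::runif(n) < cond[3])
  .restore_seed(old)
  dplyr::mutate(truth,
                alive_t0 = a0, alive_t1 = a1, alive_t2 = a2,
                rate_t0 = ifelse(a0, .data$rate_t0, 0),
                rate_t1 = ifelse(a1, .data$rate_t1, 0),
                rate_t2 = ifelse(a2, .data$rate_t2, 0))
}

#' Per-well summary of a truth table
#'
#' @param truth a cell-level truth tibble.
#' @param geometry the chip geometry (supplies wells with zero cells).
#' @return Tibble with one row per well: `well_id`, `n_cells`, and (when
#'   present in `truth`) per-phase live counts and total secreted mass-rate.
#' @export
truth_wells <- function(truth, geometry) {
  base <- tibble::tibble(well_id = well_centers(geometry)$well_id)
  if (nrow(truth) == 0) return(dplyr::mutate(base, n_cells = 0L))
  per <- dplyr::summarise(dplyr::group_by(truth, .data$well_id),
                          n_cells = dplyr::n(), .groups = "drop")
  if ("alive_t0" %in% names(truth)) {
    extra <- dplyr::summarise(
      dplyr::group_by(truth, .data$well_id),
      n_live_t0 = sum(.data$alive_t0), n_live_t1 = sum(.data$alive_t1),
      n_live_t2 = sum(.data$alive_t2),
      well_rate_t0 = sum(.data$rate_t0), well_rate_t1 = sum(.data$rate_t1),
      well_rate_t2 = sum(.data$rate_t2), .groups = "drop")
    per <- dplyr::left_join(per, extra, by = "well_id")
  }
  out <- dplyr::left_join(base, per, by = "well_id")
  out$n_cells[is.na(out$n_cells)] <- 0L
  if ("n_live_t0" %in% names(out)) {
    for (cc in grep("^(n_live|well_rate)", names(out), value = TRUE)) {
      out[[cc]][is.na(out[[cc]])] <- 0
    }
  }
  out
}
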