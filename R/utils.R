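# Internal helpers: deterministic seed substreams, validation, small math.

#' Derive a deterministic substream seed from a master seed and a stage name
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so any stage can be re-run alone and reproduce its output.
#'
#' @param master integer master seed.
#' @param stage character stage name (e.g. `"seed_cells"`).
#' @return An integer seed, strictly below 2^31.
#' @export
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% 1048573
  as.integer((abs(master) * 2038074743 + h * 97 + 11) %% 2147483629)
}

fw_stop <- function(..., class) {
  rlang::abort(paste0(...), class = c(class, "fw_error"))
}

check_probs <- function(p, what, tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol) {
    fw_stop(what, " must be non-negative and sum to 1 (got sum ",
            format(sum(p)), ")", class = "fw_config_error")
  }
  invisible(p)
}

# lognormal meanlog/sdlog from arithmetic mean and CV
lnorm_params <- function(mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
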