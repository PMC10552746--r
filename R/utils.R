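# Internal helpers: classed errors and seed derivation.

abort_config <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("lumitrf_config_error", "lumitrf_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_contract <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("lumitrf_contract_error", "lumitrf_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

abort_schema <- function(msg, call = sys.call(-1)) {
  stop(structure(
    class = c("lumitrf_schema_error", "lumitrf_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministically maps a master seed plus one or more integer indices
#' (e.g. subject number, trial number) to a new seed, so that any part of a
#' simulated cohort can be regenerated in isolation. Uses a
#' Lehmer-style multiplicative hash over the Mersenne prime 2^31 - 1, so
#' derived seeds always fit a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the child stream.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647  # 2^31 - 1
  x <- as.numeric(master) %% m
  for (idx in c(...)) {
    # 48271 is the MINSTD multiplier; the +1 offsets index 0
    x <- (x * 48271 + as.numeric(idx) + 1) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
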