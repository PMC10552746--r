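# Constrained random luminance sequences and session/trial plans.
#
# The stimulus side of the luminance-tagging design: on every video frame
# (100 Hz) the foreground and background of a figure texture take independent
# random luminance values, subject to a minimum per-frame luminance difference
# that keeps the figure visible. Uniform-texture trials carry a single
# unconstrained luminance stream.

#' Stimulus configuration
#'
#' Bundles the luminance range, the per-frame minimum foreground/background
#' luminance difference, the display frame rate and the trial duration.
#' Defaults are the study conditions: luminance spanning 4.64 to
#' 100.94 cd/m^2, a minimum per-frame difference of 29.91 cd/m^2
#' (a group psychophysical segregation threshold), 100 Hz frames and 5 s
#' trials.
#'
#' @param lum_min,lum_max luminance range in cd/m^2.
#' @param min_diff minimum per-frame `|foreground - background|` in cd/m^2.
#' @param frame_rate display frame rate in Hz.
#' @param trial_duration trial length in seconds.
#' @return an object of class `stimulus_config`.
#' @export
stimulus_config <- function(lum_min = 4.64, lum_max = 100.94,
                            min_diff = 29.91, frame_rate = 100,
                            trial_duration = 5) {
  if (!is.numeric(lum_min) || !is.numeric(lum_max) || lum_max <= lum_min)
    abort_config("lum_max must exceed lum_min")
  if (min_diff < 0) abort_config("min_diff must be non-negative")
  if (lum_max - lum_min < min_diff)
    abort_config(sprintf(
      "infeasible configuration: lum_max - lum_min = %.4g < min_diff = %.4g",
      lum_max - lum_min, min_diff))
  if (frame_rate <= 0) abort_config("frame_rate must be positive")
  if (trial_duration < 0) abort_config("trial_duration must be non-negative")
  structure(
    list(lum_min = lum_min, lum_max = lum_max, min_diff = min_diff,
         frame_rate = frame_rate, trial_duration = trial_duration),
    class = "stimulus_config")
}

n_frames <- function(config) round(config$frame_rate * config$trial_duration)

#' Generate a constrained foreground/background luminance sequence pair
#'
#' Draws, for every frame independently, a (foreground, background) pair of
#' luminance values uniform on `[lum_min, lum_max]`, rejecting and redrawing
#' any frame whose absolute difference falls below `min_diff`. Both streams
#' therefore share the same marginal law and neither is biased relative to
#' the other; frames are mutually independent.
#'
#' @param config a [stimulus_config()].
#' @param rng_seed integer seed; identical seeds give identical sequences.
#' @return an object of class `luminance_pair` with numeric vectors
#'   `foreground` and `background` (cd/m^2), plus `frame_rate` and
#'   `duration`.
#' @export
generate_figure_sequences <- function(config, rng_seed) {
  stopifnot(inherits(config, "stimulus_config"))
  n <- n_frames(config)
  set.seed(rng_seed)
  fg <- numeric(n)
  bg <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    a <- stats::runif(length(todo), config$lum_min, config$lum_max)
    b <- stats::runif(length(todo), config$lum_min, config$lum_max)
    ok <- abs(a - b) >= config$min_diff
    fg[todo[ok]] <- a[ok]
    bg[todo[ok]] <- b[ok]
    todo <- todo[!ok]
  }
  structure(
    list(foreground = fg, background = bg,
         frame_rate = config$frame_rate, duration = config$trial_duration),
    class = "luminance_pair")
}

#' Generate a uniform-texture luminance sequence
#'
#' One unconstrained stream: i.i.d. uniform draws on `[lum_min, lum_max]`,
#' one per frame.
#'
#' @inheritParams generate_figure_sequences
#' @return an object of class `uniform_sequence` with a numeric `luminance`
#'   vector (cd/m^2), `frame_rate` and `duration`.
#' @export
generate_uniform_sequence <- function(config, rng_seed) {
  stopifnot(inherits(config, "stimulus_config"))
  n <- n_frames(config)
  set.seed(rng_seed)
  structure(
    list(luminance = stats::runif(n, config$lum_min, config$lum_max),
         frame_rate = config$frame_rate, duration = config$trial_duration),
    class = "uniform_sequence")
}

#' Generate a session plan with exact probe-trial bookkeeping
#'
#' Lays out the trials of one recording session. Each condition gets
#' `n_trials_per_condition` trials; trial order is randomly interleaved.
#' Within each condition, exactly `round(probe_fraction * n)` trials are
#' probe trials (the behavioural catch trials in which the texture briefly
#' switches type), chosen uniformly at random, with probe onsets uniform in
#' `probe_onset_window`. Probe counts are exact, not Bernoulli, so the
#' nominal probe percentage is reproduced exactly in every session.
#'
#' @param n_trials_per_condition trials per condition (default 126).
#' @param conditions character vector of condition labels.
#' @param probe_fraction fraction of probe trials per condition
#'   (default 1/6, i.e. 16.67%).
#' @param probe_onset_window numeric `(start, end)` in seconds within the
#'   trial during which a probe may start (default `c(0.25, 4.25)`).
#' @param probe_duration probe length in seconds (default 0.5).
#' @param trial_duration trial length in seconds (default 5).
#' @param rng_seed integer seed.
#' @return an object of class `session_plan`: a list with the call
#'   parameters and a `trial_records` data frame (`trial`, `condition`,
#'   `is_probe`, `probe_onset`, `seed`), where `seed` is the per-trial
#'   sequence seed derived from `rng_seed` via [derive_seed()].
#' @export
generate_session_plan <- function(n_trials_per_condition = 126,
                                  conditions = c("figure", "uniform"),
                                  probe_fraction = 1 / 6,
                                  probe_onset_window = c(0.25, 4.25),
                                  probe_duration = 0.5,
                                  trial_duration = 5,
                                  rng_seed = 1) {
  if (probe_fraction < 0 || probe_fraction > 1)
    abort_config("probe_fraction must lie in [0, 1]")
  if (length(probe_onset_window) != 2 ||
      probe_onset_window[1] > probe_onset_window[2])
    abort_config("probe_onset_window must be an increasing (start, end) pair")
  if (probe_onset_window[2] + probe_duration > trial_duration)
    abort_config("probe window plus probe duration exceeds the trial length")
  n <- n_trials_per_condition
  n_probe <- round(probe_fraction * n)

  set.seed(rng_seed)
  records <- do.call(rbind, lapply(conditions, function(cond) {
    probes <- logical(n)
    probes[sample.int(n, n_probe)] <- TRUE
    onsets <- rep(NA_real_, n)
    onsets[probes] <- stats::runif(n_probe, probe_onset_window[1],
                                   probe_onset_window[2])
    data.frame(condition = cond, is_probe = probes, probe_onset = onsets)
  }))
  records <- records[sample.int(nrow(records)), , drop = FALSE]
  records$trial <- seq_len(nrow(records))
  records$seed <- vapply(records$trial, function(i) derive_seed(rng_seed, i),
                         integer(1))
  rownames(records) <- NULL
  records <- records[, c("trial", "condition", "is_probe", "probe_onset",
                         "seed")]
  structure(
    list(n_trials_per_condition = n, conditions = conditions,
         probe_fraction = probe_fraction,
         probe_onset_window = probe_onset_window,
         probe_duration = probe_duration, trial_duration = trial_duration,
         rng_seed = rng_seed, trial_records = records),
    class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %d trials (%s), %.2f%% probes\n",
              nrow(x$trial_records), paste(x$conditions, collapse = ", "),
              100 * x$probe_fraction))
  invisible(x)
}

#' @export
print.luminance_pair <- function(x, ...) {
  cat(sprintf(
    "<luminance_pair> %d frames @ %g Hz, fg [%.2f, %.2f], bg [%.2f, %.2f] cd/m^2\n",
    length(x$foreground), x$frame_rate, min(x$foreground), max(x$foreground),
    min(x$background), max(x$background)))
  invisible(x)
}
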