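# Forward simulation: linear convolution of luminance sequences with
# ground-truth TRF kernels, plus white and 1/f noise, trial bookkeeping,
# artifact injection and response-correctness flags.

#' Noise model for simulated EEG
#'
#' Additive noise is a mixture of white Gaussian noise and 1/f ("pink")
#' noise, the latter reflecting the power-law background spectrum of resting
#' EEG. Power of the pink component scales as `1/f^pink_exponent`.
#'
#' @param white_sd SD of the white component, microvolts.
#' @param pink_sd SD of the pink component, microvolts.
#' @param pink_exponent spectral exponent (power ~ 1/f^exponent).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 10, pink_sd = 10, pink_exponent = 1) {
  if (white_sd < 0 || pink_sd < 0)
    abort_config("noise SDs must be non-negative")
  structure(list(white_sd = white_sd, pink_sd = pink_sd,
                 pink_exponent = pink_exponent),
            class = "noise_model")
}

# Unit-SD 1/f^a noise of length n via spectral shaping.
pink_noise <- function(n, exponent = 1) {
  if (n < 2) return(numeric(n))
  x <- stats::rnorm(n)
  f <- seq_len(n) - 1
  f[f > n / 2] <- n - f[f > n / 2]   # two-sided frequency index
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  y <- Re(stats::fft(stats::fft(x) * scale, inverse = TRUE)) / n
  y / stats::sd(y)
}

draw_noise <- function(noise, n_channels, n_time) {
  out <- matrix(0, n_channels, n_time)
  if (noise$white_sd > 0)
    out <- out + matrix(stats::rnorm(n_channels * n_time, sd = noise$white_sd),
                        n_channels, n_time)
  if (noise$pink_sd > 0)
    for (ch in seq_len(n_channels))
      out[ch, ] <- out[ch, ] +
        noise$pink_sd * pink_noise(n_time, noise$pink_exponent)
  out
}

#' Simulate one EEG epoch from luminance streams and TRF kernels
#'
#' The epoch is the sum over streams of the causal convolution of each
#' stream (zero-order-hold upsampled from the frame rate to the acquisition
#' rate) with its kernel, plus noise. Lag zero of the kernel is aligned with
#' stimulus frame onset, and the stimulus starts at epoch time 0. Kernel
#' weights are defined per stimulus frame: when the acquisition rate
#' exceeds the frame rate, the zero-order-hold contribution is divided by
#' the upsampling factor, so the driven response amplitude does not depend
#' on the simulation rate.
#'
#' @param sequences list of numeric luminance vectors, one per stream, at
#'   `frame_rate`.
#' @param kernels list of `trf_kernel` objects, one per stream.
#' @param noise a [noise_model()], or NULL for noiseless output.
#' @param sampling_rate acquisition rate in Hz; must be an integer multiple
#'   of `frame_rate`.
#' @param frame_rate stimulus frame rate in Hz.
#' @param window_ms epoch window `(start, end)` in ms relative to stimulus
#'   onset.
#' @param rng_seed optional integer seed for the noise draw.
#' @param adapt_level adaptation luminance (cd/m^2) subtracted from every
#'   stream before convolution. The default 0 gives the pure convolution of
#'   the supplied sequences. Session simulation passes the midpoint of the
#'   luminance range, so that the EEG tracks luminance deviations around
#'   the adapting level: recorded EEG is AC-coupled and carries no standing
#'   potential proportional to absolute luminance, and before stimulus
#'   onset (deviation zero) the driven response is exactly zero.
#' @return channels x time matrix (microvolts) with attributes `time_ms`
#'   and `sampling_rate`; rownames are channel labels.
#' @export
simulate_epoch <- function(sequences, kernels, noise = NULL,
                           sampling_rate = 1000, frame_rate = 100,
                           window_ms = c(-1000, 7000), rng_seed = NULL,
                           adapt_level = 0) {
  if (length(sequences) != length(kernels))
    abort_contract("number of streams must match number of kernels")
  up <- sampling_rate / frame_rate
  if (up != round(up) || up < 1)
    abort_config("sampling_rate must be an integer multiple of frame_rate")
  dt <- 1000 / sampling_rate
  time_ms <- seq(window_ms[1], window_ms[2] - dt, by = dt)
  channels <- kernels[[1]]$channels
  epoch <- matrix(0, length(channels), length(time_ms),
                  dimnames = list(channels, NULL))
  for (s in seq_along(sequences)) {
    k <- kernels[[s]]
    if (!identical(k$channels, channels))
      abort_contract("all kernels must share one channel set")
    lag_fs <- seq(min(k$lag_ms), max(k$lag_ms), by = dt)
    k_fs <- regrid_kernel(k, lag_fs)
    stim <- rep(sequences[[s]] - adapt_level, each = up) / up
    if (length(stim) == 0) next
    n_out <- length(stim) + length(lag_fs) - 1
    # response sample i (1-based) sits at time (i-1)*dt + lag_fs[1]
    t_resp <- (seq_len(n_out) - 1) * dt + lag_fs[1]
    idx <- match(round(t_resp / dt), round(time_ms / dt))
    keep <- !is.na(idx)
    for (ch in seq_along(channels)) {
      r <- stats::convolve(stim, rev(k_fs$weights[, ch]), type = "open")
      epoch[ch, idx[keep]] <- epoch[ch, idx[keep]] + r[keep]
    }
  }
  if (!is.null(noise)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    epoch <- epoch + draw_noise(noise, length(channels), length(time_ms))
  }
  attr(epoch, "time_ms") <- time_ms
  attr(epoch, "sampling_rate") <- sampling_rate
  epoch
}

# 7 Hz Hann-windowed burst; passes the 1-40 Hz analysis band essentially
# unattenuated, so threshold rejection sees it after filtering.
artifact_burst <- function(time_ms, center_ms = 2500, dur_ms = 300,
                           amp_uv = 400) {
  env <- numeric(length(time_ms))
  inside <- abs(time_ms - center_ms) <= dur_ms / 2
  phase <- (time_ms[inside] - center_ms) / 1000
  env[inside] <- amp_uv * sin(2 * pi * 7 * phase + pi / 2) *
    0.5 * (1 + cos(2 * pi * (time_ms[inside] - center_ms) / dur_ms))
  env
}

#' Simulate a full recording session with known ground truth
#'
#' Runs [simulate_epoch()] over every trial of a [generate_session_plan()]
#' plan: figure trials convolve independent foreground and background
#' luminance streams with their respective kernels; uniform trials convolve
#' a single stream with the uniform kernel. A fixed number of trials
#' (`round(artifact_rate * n)`) receives a large low-frequency artifact
#' burst exceeding +/-100 microvolts, and `round(incorrect_rate * n)` trials
#' are flagged as behaviourally incorrect; both sets are chosen uniformly at
#' random but with exact counts, so downstream rejection rates are
#' reproducible.
#'
#' @param plan a `session_plan`.
#' @param stim_config a [stimulus_config()].
#' @param kernels named list with `foreground`, `background` and `uniform`
#'   `trf_kernel`s (see [default_kernels()]).
#' @param noise a [noise_model()] or NULL.
#' @param artifact_rate,incorrect_rate fractions in `[0, 1]`.
#' @param rng_seed master seed for the session; per-trial noise seeds are
#'   derived from it.
#' @param sampling_rate acquisition rate, Hz.
#' @param window_ms epoch window in ms.
#' @return an object of class `sim_session`: `epochs` (trials x channels x
#'   time array, microvolts), `time_ms`, `sampling_rate`, `channels`,
#'   `trial_records` (plan records plus `artifact` and `correct` columns),
#'   `sequences` (per-trial list of luminance streams), `kernels`,
#'   `stim_config`, `noise`.
#' @export
simulate_session <- function(plan, stim_config, kernels = default_kernels(),
                             noise = noise_model(),
                             artifact_rate = 0, incorrect_rate = 0,
                             rng_seed = 1, sampling_rate = 1000,
                             window_ms = c(-1000, 7000)) {
  stopifnot(inherits(plan, "session_plan"))
  if (artifact_rate < 0 || artifact_rate > 1 ||
      incorrect_rate < 0 || incorrect_rate > 1)
    abort_config("artifact_rate and incorrect_rate must lie in [0, 1]")
  # default kernels are built on a fine lag grid; align to requested montage
  channels <- kernels$uniform$channels
  rec <- plan$trial_records
  n <- nrow(rec)
  dt <- 1000 / sampling_rate
  time_ms <- seq(window_ms[1], window_ms[2] - dt, by = dt)

  adapt_level <- (stim_config$lum_min + stim_config$lum_max) / 2
  set.seed(derive_seed(rng_seed, 0))
  artifact <- logical(n)
  artifact[sample.int(n, round(artifact_rate * n))] <- TRUE
  correct <- rep(TRUE, n)
  correct[sample.int(n, round(incorrect_rate * n))] <- FALSE

  epochs <- array(0, dim = c(n, length(channels), length(time_ms)),
                  dimnames = list(NULL, channels, NULL))
  sequences <- vector("list", n)
  burst <- artifact_burst(time_ms)
  for (i in seq_len(n)) {
    if (rec$condition[i] == "figure") {
      pair <- generate_figure_sequences(stim_config, rec$seed[i])
      streams <- list(foreground = pair$foreground,
                      background = pair$background)
      ks <- list(kernels$foreground, kernels$background)
    } else {
      us <- generate_uniform_sequence(stim_config, rec$seed[i])
      streams <- list(uniform = us$luminance)
      ks <- list(kernels$uniform)
    }
    ep <- simulate_epoch(streams, ks, noise,
                         sampling_rate = sampling_rate,
                         frame_rate = stim_config$frame_rate,
                         window_ms = window_ms,
                         rng_seed = derive_seed(rng_seed, i, 7),
                         adapt_level = adapt_level)
    if (artifact[i]) {
      nonref <- !channels %in% c("TP9", "TP10")
      ep[nonref, ] <- sweep(ep[nonref, , drop = FALSE], 2, burst, `+`)
    }
    epochs[i, , ] <- ep
    sequences[[i]] <- streams
  }
  rec$artifact <- artifact
  rec$correct <- correct
  structure(
    list(epochs = epochs, time_ms = time_ms, sampling_rate = sampling_rate,
         channels = channels, trial_records = rec, sequences = sequences,
         kernels = kernels, stim_config = stim_config, noise = noise,
         adapt_level = adapt_level),
    class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %d trials x %d channels x %d samples @ %g Hz\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$sampling_rate))
  invisible(x)
}

#' Measure the simulated single-trial signal-to-noise ratio
#'
#' Ratio of stimulus-driven EEG variance to noise variance in single figure
#' trials, averaged over the fifteen analysis electrodes. Used to document
#' the operating point of the simulator defaults.
#'
#' @param kernels kernel list as in [simulate_session()].
#' @param stim_config a [stimulus_config()].
#' @param noise a [noise_model()].
#' @param n_trials trials to average over.
#' @param sampling_rate acquisition rate, Hz.
#' @param rng_seed integer seed.
#' @return mean signal power / noise power (unitless).
#' @export
measure_snr <- function(kernels = default_kernels(),
                        stim_config = stimulus_config(),
                        noise = noise_model(), n_trials = 10,
                        sampling_rate = 100, rng_seed = 1) {
  roi <- intersect(kernels$uniform$channels, unlist(default_roi_map()))
  noise_var <- noise$white_sd^2 + noise$pink_sd^2
  sig <- 0
  for (i in seq_len(n_trials)) {
    pair <- generate_figure_sequences(stim_config, derive_seed(rng_seed, i))
    ep <- simulate_epoch(list(pair$foreground, pair$background),
                         list(kernels$foreground, kernels$background),
                         noise = NULL, sampling_rate = sampling_rate,
                         frame_rate = stim_config$frame_rate,
                         window_ms = c(0, stim_config$trial_duration * 1000),
                         adapt_level = (stim_config$lum_min +
                                          stim_config$lum_max) / 2)
    sig <- sig + mean(apply(ep[roi, , drop = FALSE], 1, stats::var))
  }
  (sig / n_trials) / noise_var
}
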