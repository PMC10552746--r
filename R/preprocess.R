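# Preprocessing chain: band-pass filtering, mastoid re-referencing,
# epoching with baseline correction, amplitude-threshold rejection, and
# decimation with cropping to the analysis window.

new_epoch_set <- function(data, time_ms, sampling_rate, channels, retained) {
  structure(
    list(data = data, time_ms = time_ms, sampling_rate = sampling_rate,
         channels = channels, retained = retained),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz, t in [%g, %g] ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

apply_channelwise <- function(x, fun) {
  # x: channels x time matrix, or epochs x channels x time array
  if (is.matrix(x)) {
    t(apply(x, 1, fun))
  } else {
    out <- x
    for (e in seq_len(dim(x)[1]))
      out[e, , ] <- t(apply(x[e, , , drop = TRUE], 1, fun))
    out
  }
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth IIR band-pass of the stated order forward and
#' backward (zero-phase, via `signal::filtfilt`), channel by channel.
#' Zero-phase filtering doubles the effective order but introduces no group
#' delay, so component latencies are not shifted. The default 1-40 Hz band
#' removes DC and slow drift as well as line noise.
#'
#' @param x channels x time matrix, epochs x channels x time array, or an
#'   `epoch_set` / `sim_session`.
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order (default 2).
#' @param sampling_rate Hz; taken from the object when it carries one.
#' @return same shape/class as the input.
#' @export
bandpass_filter <- function(x, low_hz = 1, high_hz = 40, order = 2,
                            sampling_rate = NULL) {
  fs <- sampling_rate %||% x$sampling_rate
  if (is.null(fs)) abort_config("sampling_rate must be supplied")
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= fs / 2)
    abort_config("need 0 < low_hz < high_hz < Nyquist")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  filt1 <- function(v) signal::filtfilt(bf, v)
  if (is.list(x)) {
    x$epochs <- if (!is.null(x$epochs)) apply_channelwise(x$epochs, filt1)
    if (!is.null(x$data)) x$data <- apply_channelwise(x$data, filt1)
    x
  } else {
    apply_channelwise(x, filt1)
  }
}

#' Re-reference to the mean of reference channels
#'
#' Subtracts, sample by sample, the mean of the named reference channels
#' (default: averaged mastoids TP9/TP10) from every channel.
#'
#' @param x channels x time matrix with rownames, epochs x channels x time
#'   array with channel dimnames, or an `epoch_set` / `sim_session`.
#' @param reference_labels channel labels of the reference set.
#' @return same shape/class as the input.
#' @export
rereference <- function(x, reference_labels = c("TP9", "TP10")) {
  reref_mat <- function(m, channels) {
    missing <- setdiff(reference_labels, channels)
    if (length(missing) > 0)
      abort_contract(paste("reference channels missing from montage:",
                           paste(missing, collapse = ", ")))
    ref <- colMeans(m[channels %in% reference_labels, , drop = FALSE])
    sweep(m, 2, ref, `-`)
  }
  if (is.matrix(x)) return(reref_mat(x, rownames(x)))
  channels <- x$channels
  arr_name <- if (!is.null(x$epochs)) "epochs" else "data"
  arr <- x[[arr_name]]
  for (e in seq_len(dim(arr)[1]))
    arr[e, , ] <- reref_mat(arr[e, , , drop = TRUE], channels)
  x[[arr_name]] <- arr
  x
}

#' Cut a continuous recording into baseline-corrected epochs
#'
#' Extracts a fixed window around each stimulus onset and subtracts, per
#' epoch and channel, the mean over the baseline interval. Onsets whose
#' window would run past either end of the recording are dropped with a
#' warning.
#'
#' @param recording list with `data` (channels x time matrix), `sampling_rate`
#'   (Hz) and `channels`.
#' @param onsets_s stimulus onsets in seconds from recording start.
#' @param window_ms epoch window `(start, end)` in ms relative to onset.
#' @param baseline_ms baseline interval in ms relative to onset.
#' @return an `epoch_set`; `retained` holds the indices of the onsets kept.
#' @export
epoch_and_baseline <- function(recording, onsets_s,
                               window_ms = c(-1000, 7000),
                               baseline_ms = c(-1000, 0)) {
  fs <- recording$sampling_rate
  dt <- 1000 / fs
  n_time <- ncol(recording$data)
  rel <- seq(window_ms[1], window_ms[2] - dt, by = dt)
  onset_idx <- round(onsets_s * fs) + 1
  first <- onset_idx + round(window_ms[1] / dt)
  last <- first + length(rel) - 1
  ok <- first >= 1 & last <= n_time
  if (any(!ok))
    warning(sprintf("dropping %d epoch(s) outside the recording bounds",
                    sum(!ok)))
  keep <- which(ok)
  data <- array(0, dim = c(length(keep), nrow(recording$data), length(rel)),
                dimnames = list(NULL, recording$channels, NULL))
  for (j in seq_along(keep)) {
    i <- keep[j]
    data[j, , ] <- recording$data[, first[i]:last[i]]
  }
  es <- new_epoch_set(data, rel, fs, recording$channels, keep)
  baseline_correct(es, baseline_ms)
}

#' Baseline-correct an epoch set
#'
#' Per epoch and channel, subtracts the mean amplitude over the baseline
#' interval.
#'
#' @param epochs an `epoch_set` (or `sim_session`, corrected in place).
#' @param baseline_ms interval in ms relative to stimulus onset.
#' @return object of the same class.
#' @export
baseline_correct <- function(epochs, baseline_ms = c(-1000, 0)) {
  arr_name <- if (!is.null(epochs$epochs)) "epochs" else "data"
  arr <- epochs[[arr_name]]
  sel <- epochs$time_ms >= baseline_ms[1] & epochs$time_ms < baseline_ms[2]
  if (!any(sel)) abort_config("baseline interval contains no samples")
  n_ch <- dim(arr)[2]
  for (e in seq_len(dim(arr)[1])) {
    bl <- rowMeans(matrix(arr[e, , sel, drop = FALSE], nrow = n_ch))
    arr[e, , ] <- matrix(arr[e, , , drop = FALSE], nrow = n_ch) - bl
  }
  epochs[[arr_name]] <- arr
  epochs
}

#' Reject epochs by amplitude threshold and behavioural correctness
#'
#' Drops every epoch in which any channel strictly exceeds the amplitude
#' threshold at any sample (an epoch peaking at exactly the threshold is
#' retained), and every epoch flagged as behaviourally incorrect.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @param correct_flags optional logical vector, one per epoch; `FALSE`
#'   marks an incorrect behavioural response.
#' @return an `epoch_set` restricted to the retained epochs, with
#'   `retained` mapping back to the original trial indices.
#' @export
reject_epochs <- function(epochs, threshold_uv = 100, correct_flags = NULL) {
  n <- dim(epochs$data)[1]
  if (!is.null(correct_flags) && length(correct_flags) != n)
    abort_contract("correct_flags length must match the number of epochs")
  peak <- apply(abs(epochs$data), 1, max)
  keep <- peak <= threshold_uv
  if (!is.null(correct_flags)) keep <- keep & correct_flags
  if (!any(keep))
    abort_contract("no epochs survive rejection; estimation is impossible")
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$retained <- epochs$retained[keep]
  epochs
}

#' Decimate and crop epochs to the analysis window
#'
#' Downsamples by an integer factor (plain subsampling: the preceding 1-40 Hz
#' band-pass already bounds the spectrum below the new Nyquist, so no extra
#' anti-alias filter is applied) and crops to the analysis window. The
#' default crop, 500 to 4500 ms, discards the stimulus onset and offset
#' transients; sample centers in `[start, end)` are kept, giving 400 samples
#' per epoch at 100 Hz.
#'
#' @param epochs an `epoch_set`.
#' @param target_hz new sampling rate; must divide the current rate.
#' @param crop_ms analysis window `(start, end)` in ms.
#' @return an `epoch_set` at `target_hz` over `crop_ms`.
#' @export
resample_and_crop <- function(epochs, target_hz = 100,
                              crop_ms = c(500, 4500)) {
  fac <- epochs$sampling_rate / target_hz
  if (fac != round(fac) || fac < 1)
    abort_config("target_hz must divide the sampling rate")
  idx <- seq(1, length(epochs$time_ms), by = fac)
  t_new <- epochs$time_ms[idx]
  keep <- t_new >= crop_ms[1] & t_new < crop_ms[2]
  if (!any(keep)) abort_config("crop window contains no samples")
  epochs$data <- epochs$data[, , idx[keep], drop = FALSE]
  epochs$time_ms <- t_new[keep]
  epochs$sampling_rate <- target_hz
  epochs
}

#' Run the full preprocessing chain on a simulated session
#'
#' Band-pass filter, re-reference to the averaged mastoids, baseline-correct,
#' reject artifact and incorrect-response epochs, then decimate and crop to
#' the analysis window. Steps can be switched off individually (e.g. when
#' the session was already simulated at the analysis rate).
#'
#' @param session a `sim_session`.
#' @param low_hz,high_hz,filter_order band-pass settings; `filter = FALSE`
#'   skips filtering.
#' @param reference_labels mastoid labels, or NULL to skip re-referencing.
#' @param baseline_ms baseline interval, or NULL to skip.
#' @param threshold_uv rejection threshold in microvolts.
#' @param target_hz,crop_ms decimation and crop settings.
#' @param filter logical; apply the band-pass.
#' @param artifact_hook optional function `epoch_set -> epoch_set` applied
#'   after re-referencing, where an ICA-based ocular-artifact stage would
#'   sit for real recordings. Synthetic sessions contain no ocular
#'   components, so the default is a no-op and threshold rejection is the
#'   only artifact rule.
#' @return an `epoch_set` of analysis-ready epochs; `retained` indexes the
#'   surviving trials of `session$trial_records`.
#' @export
preprocess_session <- function(session, low_hz = 1, high_hz = 40,
                               filter_order = 2,
                               reference_labels = c("TP9", "TP10"),
                               baseline_ms = c(-1000, 0),
                               threshold_uv = 100, target_hz = 100,
                               crop_ms = c(500, 4500), filter = TRUE,
                               artifact_hook = NULL) {
  es <- new_epoch_set(session$epochs, session$time_ms,
                      session$sampling_rate, session$channels,
                      seq_len(dim(session$epochs)[1]))
  if (filter)
    es$data <- apply_channelwise(es$data, local({
      bf <- signal::butter(filter_order,
                           c(low_hz, high_hz) / (session$sampling_rate / 2),
                           type = "pass")
      function(v) signal::filtfilt(bf, v)
    }))
  if (!is.null(reference_labels)) es <- rereference(es, reference_labels)
  if (!is.null(artifact_hook)) es <- artifact_hook(es)
  if (!is.null(baseline_ms)) es <- baseline_correct(es, baseline_ms)
  es <- reject_epochs(es, threshold_uv, session$trial_records$correct)
  resample_and_crop(es, target_hz, crop_ms)
}
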