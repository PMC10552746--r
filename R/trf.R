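# Ridge-regression TRF estimation on lagged stimulus designs, tsVEP
# subtraction, and the trial-shuffle null control.
#
# The encoding model is r(t, n) = sum_tau omega(tau, n) s(t - tau) + eps:
# each channel's EEG is a lagged linear function of the luminance sequence.
# Estimation stacks per-trial lagged design blocks (zero-padded at trial
# boundaries, so no information leaks across trials) and solves the ridge
# normal equations per channel.

#' Estimator configuration
#'
#' @param lag_min_ms,lag_max_ms lag range in ms (default 0 to 800 ms, the
#'   plotted TRF axis); the lag grid steps at the sampling interval.
#' @param ridge_lambda ridge penalty (default 1, applied to z-scored data
#'   with an identity penalty matrix).
#' @param joint_streams when TRUE (default) the foreground and background
#'   lagged designs sit side by side in one regression, so variance shared
#'   through the luminance-difference constraint is split rather than
#'   double-counted; FALSE fits each stream alone.
#' @param normalize z-score stimuli and EEG over the concatenated retained
#'   trials before fitting (default TRUE).
#' @param min_trials below this retained-trial count the estimate is
#'   flagged with a warning.
#' @return an object of class `estimator_config`.
#' @export
estimator_config <- function(lag_min_ms = 0, lag_max_ms = 800,
                             ridge_lambda = 1, joint_streams = TRUE,
                             normalize = TRUE, min_trials = 10) {
  if (lag_max_ms <= lag_min_ms) abort_config("lag_max_ms must exceed lag_min_ms")
  if (ridge_lambda < 0) abort_config("ridge_lambda must be non-negative")
  structure(list(lag_min_ms = lag_min_ms, lag_max_ms = lag_max_ms,
                 ridge_lambda = ridge_lambda, joint_streams = joint_streams,
                 normalize = normalize, min_trials = min_trials),
            class = "estimator_config")
}

#' Build the lagged design block for one trial
#'
#' Column j holds the stimulus delayed by `lag_axis[j]`:
#' `X[t, j] = s[t - lag_j]`, zero outside the trial. Each trial forms an
#' independent block, so concatenated designs never mix samples across
#' trials.
#'
#' @param sequence numeric stimulus vector (one value per EEG sample).
#' @param lag_axis lags in ms; each must be an integer number of samples at
#'   `sampling_rate`.
#' @param sampling_rate Hz.
#' @return `length(sequence)` x `length(lag_axis)` matrix.
#' @export
build_lagged_design <- function(sequence, lag_axis, sampling_rate = 100) {
  lag_samp <- lag_axis * sampling_rate / 1000
  if (any(abs(lag_samp - round(lag_samp)) > 1e-9))
    abort_config("lag axis is not aligned to the sampling step")
  lag_samp <- as.integer(round(lag_samp))
  n <- length(sequence)
  X <- matrix(0, n, length(lag_samp))
  for (j in seq_along(lag_samp)) {
    d <- lag_samp[j]
    if (d >= 0) {
      if (d < n) X[(d + 1):n, j] <- sequence[1:(n - d)]
    } else {
      if (-d < n) X[1:(n + d), j] <- sequence[(1 - d):n]
    }
  }
  X
}

#' Z-score stimuli and EEG over concatenated trials
#'
#' Pools the retained trials of one condition and z-scores each stimulus
#' stream and each EEG channel over the concatenation (mean 0, SD 1), the
#' normalization applied before TRF fitting.
#'
#' @param sequences list (one element per trial) of named lists of stimulus
#'   vectors at the EEG sampling rate.
#' @param epochs trials x channels x time array.
#' @return list with normalized `sequences` and `epochs`.
#' @export
normalize_concatenated <- function(sequences, epochs) {
  stream_names <- names(sequences[[1]])
  for (s in stream_names) {
    pooled <- unlist(lapply(sequences, `[[`, s))
    mu <- mean(pooled); sdv <- stats::sd(pooled)
    if (!is.finite(sdv) || sdv == 0)
      abort_contract(sprintf("stimulus stream '%s' has zero variance", s))
    for (i in seq_along(sequences))
      sequences[[i]][[s]] <- (sequences[[i]][[s]] - mu) / sdv
  }
  for (ch in seq_len(dim(epochs)[2])) {
    pooled <- as.vector(epochs[, ch, ])
    mu <- mean(pooled); sdv <- stats::sd(pooled)
    if (!is.finite(sdv) || sdv == 0)
      abort_contract(sprintf("EEG channel %d has zero variance", ch))
    epochs[, ch, ] <- (epochs[, ch, ] - mu) / sdv
  }
  list(sequences = sequences, epochs = epochs)
}

#' Pooled normalization constants across conditions
#'
#' Computes a single stimulus scale (over every luminance stream of every
#' trial, all in cd/m^2) and per-channel EEG scales over all retained
#' trials of all conditions. Using one set of constants for every
#' condition keeps the condition TRFs in identical units, which the tsVEP
#' subtraction requires: with per-condition scaling, identical underlying
#' kernels would not cancel, because the constrained figure streams have a
#' slightly larger SD than the uniform stream.
#'
#' @param sequences list over trials of named lists of stimulus vectors.
#' @param epochs trials x channels x time array covering the same trials.
#' @return list with `stim_mean`, `stim_sd`, `chan_mean`, `chan_sd`.
#' @export
pooled_normalization <- function(sequences, epochs) {
  pooled <- unlist(lapply(sequences, unlist), use.names = FALSE)
  stim_sd <- stats::sd(pooled)
  if (!is.finite(stim_sd) || stim_sd == 0)
    abort_contract("pooled stimulus has zero variance")
  n_ch <- dim(epochs)[2]
  chan_mean <- numeric(n_ch); chan_sd <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    v <- as.vector(epochs[, ch, ])
    chan_mean[ch] <- mean(v)
    chan_sd[ch] <- stats::sd(v)
    if (!is.finite(chan_sd[ch]) || chan_sd[ch] == 0)
      abort_contract(sprintf("EEG channel %d has zero variance", ch))
  }
  list(stim_mean = mean(pooled), stim_sd = stim_sd,
       chan_mean = chan_mean, chan_sd = chan_sd)
}

apply_normalization <- function(sequences, epochs, nc) {
  sequences <- lapply(sequences, function(streams)
    lapply(streams, function(s) (s - nc$stim_mean) / nc$stim_sd))
  for (ch in seq_len(dim(epochs)[2]))
    epochs[, ch, ] <- (epochs[, ch, ] - nc$chan_mean[ch]) / nc$chan_sd[ch]
  list(sequences = sequences, epochs = epochs)
}

#' Solve the ridge normal equations
#'
#' Returns `w` solving `(X'X + lambda I) w = X'y` for each response column;
#' no intercept (the data are z-scored) and an identity penalty matrix.
#'
#' @param design rows = samples, columns = lagged regressors.
#' @param response numeric vector or samples x channels matrix.
#' @param ridge_lambda penalty, >= 0.
#' @return regressors x channels weight matrix.
#' @export
fit_ridge <- function(design, response, ridge_lambda = 1) {
  response <- as.matrix(response)
  if (nrow(design) != nrow(response))
    abort_contract("design and response must have the same number of rows")
  if (ridge_lambda < 0) abort_config("ridge_lambda must be non-negative")
  A <- crossprod(design) + ridge_lambda * diag(ncol(design))
  b <- crossprod(design, response)
  w <- tryCatch(
    solve(A, b),
    error = function(e) {
      if (ridge_lambda == 0)
        abort_config("singular system with ridge_lambda = 0; use lambda > 0")
      stop(e)
    })
  dimnames(w) <- list(NULL, colnames(response))
  w
}

new_trf_estimate <- function(weights, lag_ms, channels, condition,
                             subject_id = NULL, flagged = FALSE) {
  structure(
    list(weights = weights, lag_ms = lag_ms, channels = channels,
         condition = condition, subject_id = subject_id, flagged = flagged),
    class = "trf_kernel")
}

#' Estimate condition-specific TRFs from preprocessed epochs
#'
#' Figure trials (two streams per trial, `foreground` and `background`)
#' yield one kernel per stream; with `joint_streams` both lagged designs
#' enter one regression. Uniform trials (single `uniform` stream) yield the
#' uniform kernel. Stimuli and EEG are z-scored over the concatenated
#' retained trials before fitting, and each trial contributes an
#' independent zero-padded design block.
#'
#' @param epoch_set analysis-ready `epoch_set` (same rate as the stimulus).
#' @param sequences list, one element per retained epoch, of named lists of
#'   stimulus vectors (`foreground`/`background`, or `uniform`) sampled on
#'   the analysis-rate grid starting at stimulus onset (t = 0). When the
#'   epochs are cropped (e.g. to 500-4500 ms) the full within-trial
#'   stimulus must still be supplied: lagged regressors for the first
#'   samples of the analysis window then use the true stimulus history
#'   rather than zero padding, which would otherwise bias the fit.
#' @param config an [estimator_config()].
#' @param subject_id optional label carried into the estimates.
#' @param norm_constants optional constants from [pooled_normalization()];
#'   when supplied (the cross-condition pipeline path) they replace the
#'   within-call z-scoring so all conditions share one scale.
#' @return named list of `trf_kernel` estimates, one per stream.
#' @export
estimate_condition_trfs <- function(epoch_set, sequences,
                                    config = estimator_config(),
                                    subject_id = NULL,
                                    norm_constants = NULL) {
  n_trials <- dim(epoch_set$data)[1]
  if (length(sequences) != n_trials)
    abort_contract("one sequence set per retained epoch is required")
  fs <- epoch_set$sampling_rate
  n_t <- dim(epoch_set$data)[3]
  dt <- 1000 / fs
  # rows of the full-stimulus lagged design matching the epoch samples
  ridx <- round(epoch_set$time_ms / dt) + 1
  n_seq <- length(sequences[[1]][[1]])
  if (any(abs(epoch_set$time_ms / dt - round(epoch_set$time_ms / dt)) > 1e-6))
    abort_contract("epoch time axis is not aligned to the stimulus grid")
  if (any(ridx < 1) || any(ridx > n_seq))
    abort_contract("epoch time axis extends beyond the supplied stimulus")
  flagged <- n_trials < config$min_trials
  if (flagged)
    warning(sprintf("only %d retained trials (< %d); estimate flagged",
                    n_trials, config$min_trials))

  lag_axis <- seq(config$lag_min_ms, config$lag_max_ms, by = 1000 / fs)
  stream_names <- names(sequences[[1]])
  epochs <- epoch_set$data
  if (config$normalize) {
    nz <- if (is.null(norm_constants)) {
      normalize_concatenated(sequences, epochs)
    } else {
      apply_normalization(sequences, epochs, norm_constants)
    }
    sequences <- nz$sequences
    epochs <- nz$epochs
  }
  Y <- do.call(rbind, lapply(seq_len(n_trials), function(i)
    t(matrix(epochs[i, , , drop = FALSE], nrow = dim(epochs)[2]))))
  colnames(Y) <- epoch_set$channels

  design_for <- function(streams) {
    do.call(rbind, lapply(seq_len(n_trials), function(i)
      do.call(cbind, lapply(streams, function(s)
        build_lagged_design(sequences[[i]][[s]], lag_axis,
                            fs)[ridx, , drop = FALSE]))))
  }
  n_lag <- length(lag_axis)
  if (config$joint_streams || length(stream_names) == 1) {
    X <- design_for(stream_names)
    w <- fit_ridge(X, Y, config$ridge_lambda)
    out <- lapply(seq_along(stream_names), function(k)
      new_trf_estimate(w[((k - 1) * n_lag + 1):(k * n_lag), , drop = FALSE],
                       lag_axis, epoch_set$channels, stream_names[k],
                       subject_id, flagged))
  } else {
    out <- lapply(seq_along(stream_names), function(k) {
      X <- design_for(stream_names[k])
      new_trf_estimate(fit_ridge(X, Y, config$ridge_lambda),
                       lag_axis, epoch_set$channels, stream_names[k],
                       subject_id, flagged)
    })
  }
  stats::setNames(out, stream_names)
}

#' Texture-segregation VEP: subtract the uniform TRF
#'
#' The tsVEP is the elementwise difference between a figure-condition TRF
#' (foreground or background) and the uniform-texture TRF, isolating
#' segregation-specific activity from the shared sensory response to
#' luminance.
#'
#' @param kernel_a foreground or background `trf_kernel`.
#' @param kernel_uniform uniform-condition `trf_kernel` on the same lag
#'   axis and channels.
#' @return an object of class `tsvep` with `weights`, `lag_ms`, `channels`,
#'   `contrast` and `subject_id`.
#' @export
compute_tsvep <- function(kernel_a, kernel_uniform) {
  if (!isTRUE(all.equal(kernel_a$lag_ms, kernel_uniform$lag_ms)) ||
      !identical(kernel_a$channels, kernel_uniform$channels))
    abort_contract("kernels must share lag axis and channel set")
  structure(
    list(weights = kernel_a$weights - kernel_uniform$weights,
         lag_ms = kernel_a$lag_ms, channels = kernel_a$channels,
         contrast = paste0(kernel_a$condition %||% "a", "-uniform"),
         subject_id = kernel_a$subject_id),
    class = "tsvep")
}

#' @export
print.tsvep <- function(x, ...) {
  cat(sprintf("<tsvep> %s: %d lags x %d channels\n", x$contrast,
              length(x$lag_ms), length(x$channels)))
  invisible(x)
}

# Random derangement by rejection; expected < 3 draws.
random_derangement <- function(n) {
  if (n < 2) abort_contract("a derangement needs at least 2 trials")
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Trial-shuffle null control for TRF estimation
#'
#' Re-estimates the TRFs after permuting the trial-to-sequence pairing by a
#' random derangement (no trial keeps its own sequence), leaving everything
#' else identical. Since the shuffled stimuli are independent of the EEG,
#' the resulting TRF should be flat and noisy; comparing its RMS with the
#' veridical estimate validates that the TRF reflects stimulus-specific
#' tracking.
#'
#' @inheritParams estimate_condition_trfs
#' @param rng_seed integer seed for the permutation.
#' @return as [estimate_condition_trfs()], with attribute `"permutation"`.
#' @export
shuffle_control_trf <- function(epoch_set, sequences,
                                config = estimator_config(),
                                rng_seed = 1, subject_id = NULL) {
  n <- dim(epoch_set$data)[1]
  set.seed(rng_seed)
  perm <- random_derangement(n)
  est <- estimate_condition_trfs(epoch_set, sequences[perm], config,
                                 subject_id)
  attr(est, "permutation") <- perm
  est
}

#' Average kernels or tsVEPs across subjects
#'
#' Elementwise mean of the weight matrices (grand average), the form in
#' which TRF waveforms are reported and plotted.
#'
#' @param kernels list of `trf_kernel` or `tsvep` objects on a common lag
#'   axis and channel set.
#' @return an object of the same class with averaged weights.
#' @export
average_kernels <- function(kernels) {
  k1 <- kernels[[1]]
  for (k in kernels[-1])
    if (!isTRUE(all.equal(k$lag_ms, k1$lag_ms)) ||
        !identical(k$channels, k1$channels))
      abort_contract("kernels must share lag axis and channel set")
  out <- k1
  out$weights <- Reduce(`+`, lapply(kernels, `[[`, "weights")) /
    length(kernels)
  out$subject_id <- NULL
  out
}

#' Root-mean-square amplitude of a kernel or tsVEP
#'
#' @param kernel a `trf_kernel` or `tsvep`.
#' @param channels optional channel subset.
#' @return scalar RMS over lags and channels.
#' @export
kernel_rms <- function(kernel, channels = NULL) {
  w <- kernel$weights
  if (!is.null(channels)) w <- w[, kernel$channels %in% channels, drop = FALSE]
  sqrt(mean(w^2))
}
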