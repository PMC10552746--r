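make_recording <- function(data, fs, channels = rownames(data)) {
  list(data = data, sampling_rate = fs, channels = channels)
}

test_that("band-pass keeps the passband and rejects out-of-band tones", {
  fs <- 1000
  t <- seq(0, 8, by = 1 / fs)
  mid <- seq(2 * fs, 6 * fs)  # avoid filter edge transients
  amp <- function(f) {
    x <- matrix(sin(2 * pi * f * t), nrow = 1)
    y <- bandpass_filter(x, 1, 40, 2, sampling_rate = fs)
    max(abs(y[1, mid]))
  }
  # analytic zero-phase Butterworth magnitude oracle: |H(e^iw)|^2
  bf <- signal::butter(2, c(1, 40) / (fs / 2), type = "pass")
  gain2 <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
          sum(bf$a * z^(seq_along(bf$a) - 1)))^2
  }
  expect_equal(amp(10), gain2(10), tolerance = 0.02)
  expect_equal(amp(10), 1, tolerance = 0.05)
  expect_equal(amp(0.1), gain2(0.1), tolerance = 0.05)
  expect_equal(amp(50), gain2(50), tolerance = 0.05)
  expect_lt(amp(0.1), 0.1)   # >90% attenuation well below the band
  expect_lt(amp(50), 0.5)    # gentler order-2 rolloff just above the band
  z <- bandpass_filter(matrix(0, 2, 1000), 1, 40, 2, sampling_rate = fs)
  expect_true(all(z == 0))
  expect_error(bandpass_filter(matrix(0, 1, 100), 1, 600, 2,
                               sampling_rate = fs),
               class = "lumitrf_config_error")
})

test_that("re-referencing subtracts the mastoid mean exactly", {
  set.seed(1)
  ch <- c("O1", "Cz", "TP9", "TP10")
  x <- matrix(rnorm(4 * 200), 4, 200, dimnames = list(ch, NULL))
  y <- rereference(x)
  ref <- colMeans(x[c("TP9", "TP10"), ])
  for (c in ch) expect_equal(y[c, ], x[c, ] - ref)

  # zero references leave data unchanged; equal channels go to zero
  x0 <- x; x0["TP9", ] <- 0; x0["TP10", ] <- 0
  expect_equal(rereference(x0), x0)
  xeq <- matrix(rep(rnorm(200), each = 4), 4, 200,
                dimnames = list(ch, NULL))
  expect_true(all(abs(rereference(xeq)) < 1e-12))

  expect_error(rereference(x[1:2, ]), class = "lumitrf_contract_error")
  # idempotence: once the reference mean is zero, again is a no-op
  expect_equal(rereference(y), y)
})

test_that("epoching and baseline correction match a brute-force loop", {
  set.seed(2)
  fs <- 100
  ch <- c("O1", "Oz")
  rec <- make_recording(matrix(rnorm(2 * 3000), 2, 3000,
                               dimnames = list(ch, NULL)), fs)
  onsets <- c(5, 12)
  es <- epoch_and_baseline(rec, onsets, window_ms = c(-1000, 7000),
                           baseline_ms = c(-1000, 0))
  expect_equal(dim(es$data), c(2, 2, 800))
  for (e in 1:2) for (c in 1:2) {
    i0 <- onsets[e] * fs + 1
    raw <- rec$data[c, (i0 - 100):(i0 + 699)]
    expect_equal(es$data[e, c, ], raw - mean(raw[1:100]))
  }
  # constant signal is zeroed; onsets beyond the record edge are dropped
  const <- make_recording(matrix(5, 2, 3000, dimnames = list(ch, NULL)), fs)
  expect_true(all(epoch_and_baseline(const, c(5))$data == 0))
  expect_warning(es2 <- epoch_and_baseline(rec, c(5, 28)), "bounds")
  expect_identical(es2$retained, 1L)
  # baseline correction is idempotent
  expect_equal(baseline_correct(es), es)
})

test_that("rejection threshold is strict and correctness flags are honored", {
  data <- array(0, dim = c(3, 2, 100))
  data[1, 1, 50] <- 101   # above threshold -> rejected
  data[2, 2, 10] <- 100   # exactly at threshold -> retained
  es <- lumitrf:::new_epoch_set(data, seq(0, 990, 10), 100, c("O1", "Oz"), 1:3)
  kept <- reject_epochs(es, 100)
  expect_identical(kept$retained, c(2L, 3L))
  kept2 <- reject_epochs(es, 100, correct_flags = c(TRUE, FALSE, TRUE))
  expect_identical(kept2$retained, 3L)
  expect_error(reject_epochs(es, 100, correct_flags = c(F, F, F)),
               class = "lumitrf_contract_error")
})

test_that("rejection removes exactly the simulator-flagged trials", {
  plan <- generate_session_plan(30, conditions = "figure", rng_seed = 3)
  sess <- simulate_session(plan, stimulus_config(), fast_kernels(),
                           noise_model(white_sd = 1, pink_sd = 1),
                           artifact_rate = 0.2, incorrect_rate = 0,
                           rng_seed = 8, sampling_rate = 100)
  es <- preprocess_session(sess, filter = FALSE, baseline_ms = NULL)
  expect_identical(sort(es$retained),
                   which(!sess$trial_records$artifact))
})

test_that("a user artifact hook slots into the chain", {
  plan <- generate_session_plan(4, conditions = "uniform", rng_seed = 5)
  sess <- simulate_session(plan, stimulus_config(), fast_kernels(),
                           noise_model(1, 1), rng_seed = 6,
                           sampling_rate = 100)
  zero_first <- function(es) { es$data[, 1, ] <- 0; es }
  es <- preprocess_session(sess, filter = FALSE, baseline_ms = NULL,
                           artifact_hook = zero_first)
  expect_true(all(es$data[, 1, ] == 0))
  expect_false(all(es$data[, 2, ] == 0))
})

test_that("decimation preserves band-limited tones and crops to 400 samples", {
  fs <- 1000
  t_ms <- seq(-1000, 6999, by = 1)
  tone <- sin(2 * pi * 30 * t_ms / 1000)
  data <- array(0, dim = c(1, 2, length(t_ms)))
  data[1, 1, ] <- tone; data[1, 2, ] <- tone
  es <- lumitrf:::new_epoch_set(data, t_ms, fs, c("O1", "Oz"), 1L)
  dc <- resample_and_crop(es, 100, c(500, 4500))
  expect_identical(dim(dc$data)[3], 400L)
  expect_equal(dc$sampling_rate, 100)
  expect_equal(max(abs(dc$data[1, 1, ] -
                         sin(2 * pi * 30 * dc$time_ms / 1000))), 0,
               tolerance = 0.02)
  expect_error(resample_and_crop(es, 300), class = "lumitrf_config_error")
  # full-window crop at the native rate changes nothing
  same <- resample_and_crop(es, 1000, c(-1000, 7000))
  expect_equal(same$data, es$data)
})

test_that("the full chain preserves kernel recoverability without noise", {
  # 1000 Hz simulation -> filter -> reref -> baseline -> decimate -> estimate
  ks <- default_kernels()
  plan <- generate_session_plan(6, conditions = "figure", rng_seed = 21)
  sess <- simulate_session(plan, stimulus_config(), ks, noise = NULL,
                           rng_seed = 22, sampling_rate = 1000)
  # avoid zero-variance reference channels in normalization: keep raw scale
  es <- preprocess_session(sess, reference_labels = NULL)
  seqs <- lumitrf:::sequences_on_grid(sess, es)
  est <- estimate_condition_trfs(
    es, seqs, estimator_config(ridge_lambda = 1e-6, min_trials = 2,
                               normalize = FALSE))
  # the chain is linear, so the estimate equals the band-passed kernel;
  # compare against truth passed through the same 1-40 Hz filter
  # effective analysis-rate kernel: band-passed at 1000 Hz, then averaged
  # over each 10 ms frame (the zero-order-hold stimulus sums the kernel
  # across sub-samples of a frame)
  # (response at a 100 Hz sample sums the 1 kHz kernel across the ten
  # sub-samples of each preceding frame; lag 0 touches one sub-sample)
  filt_truth <- function(k) {
    fine <- lumitrf:::regrid_kernel(k, seq(0, 800, by = 1))
    bf <- signal::butter(2, c(1, 40) / 500, type = "pass")
    w <- apply(fine$weights, 2, function(v) signal::filtfilt(bf, v))
    apply(w, 2, function(v) tapply(v, c(0, rep(1:80, each = 10)), mean))
  }
  expect_gt(cor(as.vector(est$foreground$weights),
                as.vector(filt_truth(ks$foreground))), 0.99)
  expect_gt(cor(as.vector(est$background$weights),
                as.vector(filt_truth(ks$background))), 0.99)
  # and still resembles the unfiltered truth
  expect_gt(kernel_cor(est$foreground, ks$foreground), 0.9)
  expect_gt(kernel_cor(est$background, ks$background), 0.9)
})
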