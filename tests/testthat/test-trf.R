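test_that("lagged design blocks match brute-force shifting", {
  s <- c(1, 0, 0, 0, 0)
  X <- build_lagged_design(s, c(0, 10, 20), sampling_rate = 100)
  expect_equal(X, cbind(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0),
                        c(0, 0, 1, 0, 0)))
  set.seed(3)
  s2 <- rnorm(40)
  lags <- seq(0, 120, by = 10)
  X2 <- build_lagged_design(s2, lags, 100)
  for (j in seq_along(lags)) {
    d <- lags[j] / 10
    ref <- c(rep(0, d), s2)[1:40]
    expect_equal(X2[, j], ref)
  }
  expect_equal(build_lagged_design(s2, 0, 100), matrix(s2, ncol = 1))
  expect_error(build_lagged_design(s2, c(0, 5), 100),
               class = "lumitrf_config_error")
})

test_that("concatenated z-scoring is exact, idempotent, and matches pooling", {
  set.seed(4)
  seqs <- list(list(u = rnorm(50, 3, 2)), list(u = rnorm(50, 1, 4)))
  epochs <- array(rnorm(2 * 3 * 50, 5, 2), dim = c(2, 3, 50))
  nz <- normalize_concatenated(seqs, epochs)
  pooled <- unlist(lapply(nz$sequences, `[[`, "u"))
  expect_equal(mean(pooled), 0, tolerance = 1e-12)
  expect_equal(sd(pooled), 1, tolerance = 1e-12)
  for (ch in 1:3) {
    v <- as.vector(nz$epochs[, ch, ])
    expect_equal(mean(v), 0, tolerance = 1e-12)
    expect_equal(sd(v), 1, tolerance = 1e-12)
  }
  # manual pooled z-score oracle
  raw <- unlist(lapply(seqs, `[[`, "u"))
  expect_equal(pooled, (raw - mean(raw)) / sd(raw))
  # idempotence
  nz2 <- normalize_concatenated(nz$sequences, nz$epochs)
  expect_equal(nz2$epochs, nz$epochs, tolerance = 1e-12)
  # zero variance errors
  expect_error(normalize_concatenated(list(list(u = rep(1, 10))),
                                      array(rnorm(10), c(1, 1, 10))),
               class = "lumitrf_contract_error")
})

test_that("ridge solutions match the closed-form normal equations", {
  set.seed(5)
  # lambda = 0 on a well-conditioned square system is plain OLS
  X <- matrix(rnorm(64), 8, 8) + diag(8)
  y <- rnorm(8)
  expect_equal(as.vector(fit_ridge(X, y, 0)), as.vector(solve(X, y)),
               tolerance = 1e-8)
  # shrinkage limit
  expect_lt(max(abs(fit_ridge(X, y, 1e12))), 1e-9)
  # dense-inversion oracle on random instances
  for (i in 1:25) {
    X <- matrix(rnorm(50 * 8), 50, 8)
    Y <- matrix(rnorm(50 * 2), 50, 2)
    lam <- runif(1, 0.1, 10)
    W <- fit_ridge(X, Y, lam)
    W_ref <- solve(crossprod(X) + lam * diag(8)) %*% crossprod(X, Y)
    expect_lt(max(abs(W - W_ref)) / max(abs(W_ref)), 1e-8)
  }
  # singular system with lambda 0
  Xs <- cbind(1:5, 2 * (1:5))
  expect_error(fit_ridge(Xs, rnorm(5), 0), class = "lumitrf_config_error")
  expect_error(fit_ridge(X[1:4, ], rnorm(5), 1),
               class = "lumitrf_contract_error")
})

test_that("noiseless sessions are recovered essentially exactly", {
  ks <- fast_kernels(channels = roi_channels())
  # raw scale: per-channel z-scoring would rescale topographies
  fit <- fit_subject(n_trials = 8, kernels = ks, noise = NULL, seed = 31,
                     est_cfg = estimator_config(ridge_lambda = 1e-6,
                                                min_trials = 2,
                                                normalize = FALSE))
  expect_gt(kernel_cor(fit$est$foreground, ks$foreground), 0.999)
  expect_gt(kernel_cor(fit$est$background, ks$background), 0.999)
})

test_that("swapping stream labels swaps the recovered kernels", {
  ks <- fast_kernels(channels = roi_channels())
  fit <- fit_subject(n_trials = 6, kernels = ks, noise = NULL, seed = 32,
                     est_cfg = estimator_config(ridge_lambda = 1e-6, min_trials = 2,
                                                normalize = FALSE))
  swapped <- lapply(fit$seqs, function(s)
    list(foreground = s$background, background = s$foreground))
  est2 <- estimate_condition_trfs(
    fit$epochs, swapped,
    estimator_config(ridge_lambda = 1e-6, min_trials = 2, normalize = FALSE))
  expect_equal(est2$foreground$weights, fit$est$background$weights,
               tolerance = 1e-6)
  expect_equal(est2$background$weights, fit$est$foreground$weights,
               tolerance = 1e-6)
})

test_that("tsVEP subtraction is exact and validates its inputs", {
  ks <- fast_kernels()
  ts <- compute_tsvep(ks$foreground, ks$uniform)
  expect_identical(ts$weights, ks$foreground$weights - ks$uniform$weights)
  expect_identical(ts$contrast, "foreground-uniform")
  # identical inputs -> exactly zero
  expect_true(all(compute_tsvep(ks$uniform, ks$uniform)$weights == 0))
  # zero uniform kernel -> identity
  zero <- make_ground_truth_kernel(list(), ks$uniform$lag_ms,
                                   ks$uniform$channels, "uniform")
  expect_identical(compute_tsvep(ks$background, zero)$weights,
                   ks$background$weights)
  short <- lumitrf:::regrid_kernel(ks$uniform, seq(0, 400, 10))
  expect_error(compute_tsvep(ks$foreground, short),
               class = "lumitrf_contract_error")
})

test_that("matched kernels give a near-zero tsVEP through the pipeline", {
  ks <- fast_kernels()
  ks$foreground <- ks$uniform  # no segregation response
  plan <- generate_session_plan(60, rng_seed = 41)
  sess <- simulate_session(plan, stimulus_config(), ks,
                           noise_model(white_sd = 1, pink_sd = 1),
                           rng_seed = 42, sampling_rate = 100)
  rc <- run_config(sim_rate = 100, kernels = ks)
  res <- analyze_session(sess, rc)
  expect_lt(kernel_rms(res$tsveps$foreground),
            0.25 * kernel_rms(res$trfs$uniform))
  # pipeline tsVEP is bitwise the kernel difference
  expect_identical(res$tsveps$background$weights,
                   res$trfs$background$weights - res$trfs$uniform$weights)
})

test_that("shuffle controls use seed-stable derangements", {
  for (n in c(2, 3, 7, 20)) {
    set.seed(n)
    p <- lumitrf:::random_derangement(n)
    expect_identical(sort(p), 1:n)
    expect_false(any(p == seq_len(n)))
  }
  ks <- fast_kernels(channels = roi_channels())
  fit <- fit_subject(n_trials = 10, kernels = ks,
                     noise = noise_model(1, 1), seed = 51, shuffle = TRUE)
  perm <- attr(fit$shuf, "permutation")
  expect_false(any(perm == seq_along(perm)))
  again <- shuffle_control_trf(fit$epochs, fit$seqs, estimator_config(),
                               rng_seed = derive_seed(51, 9))
  expect_identical(attr(again, "permutation"), perm)
  expect_equal(again$foreground$weights, fit$shuf$foreground$weights)

  one <- lumitrf:::new_epoch_set(fit$epochs$data[1, , , drop = FALSE],
                                 fit$epochs$time_ms, 100,
                                 fit$epochs$channels, 1L)
  expect_error(shuffle_control_trf(one, fit$seqs[1], estimator_config()),
               class = "lumitrf_contract_error")
})

test_that("joint estimation controls leakage between streams", {
  # only the foreground kernel drives the EEG; recovered background
  # energy on the cohort-average estimate stays a small fraction
  ks <- fast_kernels(channels = roi_channels())
  ks$background <- make_ground_truth_kernel(list(), ks$background$lag_ms,
                                            roi_channels(), "background")
  fits <- lapply(1:6, function(s)
    fit_subject(n_trials = 30, kernels = ks,
                noise = noise_model(white_sd = 2, pink_sd = 2),
                seed = derive_seed(600, s)))
  avg_f <- average_kernels(lapply(fits, function(f) f$est$foreground))
  avg_b <- average_kernels(lapply(fits, function(f) f$est$background))
  expect_lt(kernel_rms(avg_b), 0.15 * kernel_rms(avg_f))
})

test_that("kernel averaging demands matching axes", {
  ks <- fast_kernels()
  avg <- average_kernels(list(ks$foreground, ks$background))
  expect_equal(avg$weights,
               (ks$foreground$weights + ks$background$weights) / 2)
  short <- lumitrf:::regrid_kernel(ks$uniform, seq(0, 400, 10))
  expect_error(average_kernels(list(ks$foreground, short)),
               class = "lumitrf_contract_error")
})
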