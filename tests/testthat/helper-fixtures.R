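# Shared fixtures: everything is generated in code at test time.

# Kernels on a 10 ms lag grid (the 100 Hz analysis grid); optionally on a
# reduced montage so that noiseless sessions have no zero-variance channels.
fast_kernels <- function(channels = default_montage(), gain = 1) {
  default_kernels(channels = channels, lag_axis = seq(0, 800, by = 10),
                  gain = gain)
}

roi_channels <- function() unname(unlist(default_roi_map()))

# Simulate one subject's figure-trial session at the analysis rate and
# estimate its TRFs; returns estimates (and optionally the shuffle control).
fit_subject <- function(n_trials = 40, kernels = fast_kernels(),
                        noise = noise_model(), seed = 1,
                        conditions = "figure",
                        est_cfg = estimator_config(min_trials = 2),
                        shuffle = FALSE,
                        stim_cfg = stimulus_config()) {
  plan <- generate_session_plan(n_trials, conditions = conditions,
                                rng_seed = seed)
  sess <- simulate_session(plan, stim_cfg, kernels, noise,
                           rng_seed = derive_seed(seed, 1),
                           sampling_rate = 100)
  es <- preprocess_session(sess, filter = FALSE, baseline_ms = NULL,
                           reference_labels = NULL, target_hz = 100)
  seqs <- lumitrf:::sequences_on_grid(sess, es)
  out <- list(est = estimate_condition_trfs(es, seqs, est_cfg),
              epochs = es, seqs = seqs, session = sess)
  if (shuffle)
    out$shuf <- shuffle_control_trf(es, seqs, est_cfg,
                                    rng_seed = derive_seed(seed, 9))
  out
}

truth_on <- function(kernel, lag_ms) lumitrf:::regrid_kernel(kernel, lag_ms)

kernel_cor <- function(est, truth) {
  cor(as.vector(est$weights),
      as.vector(truth_on(truth, est$lag_ms)$weights))
}

# Independent sums-of-squares oracle for the two-way within-subjects ANOVA.
# Direct textbook decomposition over subject (s), factor A and factor B.
rm_anova_oracle <- function(values) {
  ns <- dim(values)[1]; na <- dim(values)[2]; nb <- dim(values)[3]
  m <- mean(values)
  m_s <- apply(values, 1, mean)
  m_a <- apply(values, 2, mean)
  m_b <- apply(values, 3, mean)
  m_sa <- apply(values, c(1, 2), mean)
  m_sb <- apply(values, c(1, 3), mean)
  m_ab <- apply(values, c(2, 3), mean)
  ss_a <- ns * nb * sum((m_a - m)^2)
  ss_b <- ns * na * sum((m_b - m)^2)
  ss_sa <- nb * sum((m_sa - outer(m_s, rep(1, na)) -
                       outer(rep(1, ns), m_a) + m)^2)
  ss_sb <- na * sum((m_sb - outer(m_s, rep(1, nb)) -
                       outer(rep(1, ns), m_b) + m)^2)
  ss_ab <- ns * sum((m_ab - outer(m_a, rep(1, nb)) -
                       outer(rep(1, na), m_b) + m)^2)
  resid <- values
  for (s in seq_len(ns)) for (a in seq_len(na)) for (b in seq_len(nb))
    resid[s, a, b] <- values[s, a, b] - m_ab[a, b] - m_sa[s, a] -
      m_sb[s, b] + m_a[a] + m_b[b] + m_s[s] - m
  ss_abs <- sum(resid^2)
  f_a <- (ss_a / (na - 1)) / (ss_sa / ((na - 1) * (ns - 1)))
  f_b <- (ss_b / (nb - 1)) / (ss_sb / ((nb - 1) * (ns - 1)))
  f_ab <- (ss_ab / ((na - 1) * (nb - 1))) /
    (ss_abs / ((na - 1) * (nb - 1) * (ns - 1)))
  list(F = c(A = f_a, B = f_b, AB = f_ab),
       partial_eta_sq = c(A = ss_a / (ss_a + ss_sa),
                          B = ss_b / (ss_b + ss_sb),
                          AB = ss_ab / (ss_ab + ss_abs)))
}
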