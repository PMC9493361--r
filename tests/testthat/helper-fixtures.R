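# Shared fixtures, all built in code.

# deterministic sinusoid-carrier test recording: carrier_hz modulated by
# mod_hz at the given depth
am_test_recording <- function(carrier_hz, mod_hz = 10, depth = 0.5,
                              fs = 500, dur = 30, channels = 1) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- cos(2 * pi * carrier_hz * t) * (1 + depth * cos(2 * pi * mod_hz * t))
  recording(matrix(rep(x, channels), ncol = channels), fs)
}

# indices away from filter edges (drop `margin_s` seconds each side)
interior <- function(n, fs, margin_s = 2) {
  k <- round(margin_s * fs)
  (k + 1):(n - k)
}

# small random cohort_table with independent matrices and performances
random_cohort_table <- function(n_subj, n_eeg = 8, n_fnirs = 25, seed = 1) {
  withr::with_seed(seed, {
    rnd_corr <- function(k) {
      X <- matrix(rnorm(4 * k * k), 4 * k, k)
      cor(X)
    }
    mats <- lapply(seq_len(n_subj), function(s) {
      list(hbo = connectivity_matrix(rnd_corr(n_fnirs), "hbo"),
           hbr = connectivity_matrix(rnd_corr(n_fnirs), "hbr"),
           beta_m_alpha = connectivity_matrix(rnd_corr(n_eeg), "beta_m_alpha"),
           gamma_m_alpha = connectivity_matrix(rnd_corr(n_eeg), "gamma_m_alpha"))
    })
    names(mats) <- sprintf("S%02d", seq_len(n_subj))
    cohort_table(mats, runif(n_subj, 20, 95))
  })
}

# latent-direct cohort table from the generator (no signal rendering)
latent_cohort <- function(n, effect_r = 0.8, seed = 1, ...) {
  cohort_from_truth(generate_cohort(
    cohort_spec(n, effect_r = effect_r, seed = seed, ...), signals = FALSE))
}

# out-of-fold prediction correlation, 0 when predictions are constant
pred_obs_r <- function(report) {
  p <- report$predictions
  if (sd(p$predicted) == 0) 0 else cor(p$predicted, p$observed)
}
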