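# EEG feature extraction: broadband filter, modulation-pair enumeration,
# amplitude-modulation series, wICA cleaning.

test_that("broadband Butterworth passes in-band content and rejects drift", {
  fs <- 500
  t <- (0:(30 * fs - 1)) / fs
  x50 <- sin(2 * pi * 50 * t)
  out <- bandpass_broadband(recording(cbind(x50), fs))
  sel <- interior(length(t), fs)
  expect_lt(abs(sd(out$data[sel, 1]) / sd(x50[sel]) - 1), 0.05)

  drift <- sin(2 * pi * 0.01 * t)
  outd <- bandpass_broadband(recording(cbind(drift), fs))
  expect_lt(sd(outd$data[sel, 1]) / sd(drift[sel]), 0.10)

  zero <- bandpass_broadband(recording(cbind(rep(0, length(t))), fs))
  expect_equal(max(abs(zero$data)), 0)

  expect_error(bandpass_broadband(recording(cbind(rnorm(100)), fs = 150)),
               "too low")
})

test_that("modulation-pair enumeration is exactly the admissible set of 14", {
  vp <- valid_modulation_pairs()
  expect_equal(nrow(vp), 14)
  expect_true(all(c("beta_m_alpha", "gamma_m_alpha") %in% vp$name))
  expect_false("alpha_m_alpha" %in% vp$name)
  # same-band envelopes admissible only for beta and gamma
  expect_true(all(c("delta_m_delta", "theta_m_theta", "beta_m_beta",
                    "gamma_m_gamma") %in% vp$name))
  expect_false(any(duplicated(vp$name)))
  # every modulator band sits at or below its carrier band
  bands <- eeg_bands()
  lo <- stats::setNames(bands$f_low, bands$name)
  expect_true(all(lo[vp$modulator] <= lo[vp$carrier]))
})

test_that("amplitude modulation recovers a planted 10 Hz modulator", {
  # 20 Hz carrier -> beta-m-alpha; 40 Hz carrier -> gamma-m-alpha
  fs <- 500
  rec20 <- am_test_recording(20, 10, 0.5, fs, dur = 30, channels = 2)
  t <- (seq_len(nrow(rec20$data)) - 1) / fs
  truth <- 0.5 * cos(2 * pi * 10 * t)
  sel <- interior(length(t), fs)

  am <- amplitude_modulation(rec20, "beta_m_alpha")
  for (ch in 1:2) expect_gt(cor(am$data[sel, ch], truth[sel]), 0.95)

  rec40 <- am_test_recording(40, 10, 0.5, fs, dur = 30)
  amg <- amplitude_modulation(rec40, "gamma_m_alpha")
  expect_gt(cor(amg$data[sel, 1], truth[sel]), 0.95)
  # and the beta-band AM of a 40 Hz carrier is essentially empty
  amb <- amplitude_modulation(rec40, "beta_m_alpha")
  expect_lt(sd(amb$data[sel, 1]), 0.05 * sd(amg$data[sel, 1]))

  # unmodulated carrier: constant envelope has no alpha-band content
  flat <- am_test_recording(20, 10, depth = 0, fs = fs, dur = 30)
  am0 <- amplitude_modulation(flat, "beta_m_alpha")
  expect_lt(sd(am0$data[sel, 1]), 1e-3)

  expect_error(amplitude_modulation(rec20, "alpha_m_alpha"), "valid")
})

test_that("AM pipeline is channel-permutation equivariant and scale covariant", {
  fs <- 500
  set.seed(41)
  spec <- cohort_spec(3, duration_s = 20, seed = 41)
  ch <- generate_cohort(spec)
  rec <- ch$subjects[[1]]$eeg
  am <- amplitude_modulation(rec, "beta_m_alpha")

  perm <- c(3, 1, 2, 5, 4, 8, 7, 6)
  rec_p <- recording(rec$data[, perm], fs, rec$channel_labels[perm])
  am_p <- amplitude_modulation(rec_p, "beta_m_alpha")
  expect_equal(am_p$data, am$data[, perm], ignore_attr = TRUE)

  rec_s <- recording(3.7 * rec$data, fs, rec$channel_labels)
  am_s <- amplitude_modulation(rec_s, "beta_m_alpha")
  expect_equal(am_s$data, 3.7 * am$data, tolerance = 1e-10)

  # envelope is non-negative before modulation filtering, output finite
  h <- neurocpm:::fir_bandpass(12, 30, fs)
  env <- neurocpm:::hilbert_envelope(
    neurocpm:::fir_filter_zerophase(rec$data, h))
  expect_true(all(env >= 0))
  expect_true(all(is.finite(am$data)))
})

test_that("the wavelet transform reconstructs perfectly", {
  set.seed(7)
  for (n in c(256, 1000, 4096)) {
    x <- rnorm(n)
    p <- neurocpm:::pad_pow2(x, 5)
    cf <- neurocpm:::dwt_forward(p$x, 5)
    expect_equal(neurocpm:::dwt_inverse(cf)[seq_len(n)], x, tolerance = 1e-10)
  }
})

test_that("wICA preserves clean EEG and attenuates injected transients", {
  spec_clean <- cohort_spec(3, duration_s = 30, noise_sd = 0.2, seed = 5)
  clean <- generate_cohort(spec_clean)$subjects[[1]]$eeg

  out <- wica_clean(clean, wica_params(seed = 5))
  cors <- sapply(seq_len(ncol(clean$data)),
                 function(i) cor(out$data[, i], clean$data[, i]))
  expect_true(all(cors >= 0.95))

  # identical signals plus artifacts (same RNG stream up to injection)
  spec_art <- cohort_spec(3, duration_s = 30, noise_sd = 0.2, seed = 5,
                          artifacts = TRUE)
  dirty <- generate_cohort(spec_art)$subjects[[1]]$eeg
  cleaned <- wica_clean(dirty, wica_params(seed = 5))
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(cleaned$data, clean$data), rmse(dirty$data, clean$data))

  # infinite thresholds: nothing is touched beyond the ICA round trip
  untouched <- wica_clean(clean, wica_params(Inf, Inf, seed = 5))
  rel <- max(abs(untouched$data - clean$data)) / sd(clean$data)
  expect_lt(rel, 1e-6)

  # rank-deficient input is rejected with a clear message
  dup <- recording(cbind(clean$data[, 1], clean$data[, 1], clean$data[, 2]),
                   clean$fs)
  expect_error(wica_clean(dup), "rank-deficient")
})
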