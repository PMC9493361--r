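# Synthetic cohort generator: determinism, planted structure, signal-level
# ground truth.

test_that("cohort specification validates its fields", {
  expect_error(cohort_spec(2), "n_subjects")
  expect_error(cohort_spec(5, duration_s = 0), "duration_s")
  expect_error(cohort_spec(5, effect_r = 1.2), "effect_r")
  bad <- data.frame(modality = "hbo", i = 10, j = 30)
  expect_error(cohort_spec(5, predictive_edges = bad), "indices")
  bad2 <- data.frame(modality = "emg", i = 1, j = 2)
  expect_error(cohort_spec(5, predictive_edges = bad2), "modality")
})

test_that("identical spec and seed reproduce the cohort exactly", {
  spec <- cohort_spec(4, duration_s = 15, seed = 99)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$truth, b$truth)
  expect_identical(a$subjects[[2]]$eeg$data, b$subjects[[2]]$eeg$data)
  expect_identical(a$subjects[[3]]$fnirs$od_850$data,
                   b$subjects[[3]]$fnirs$od_850$data)
  # and the generator does not leak state into the caller's RNG
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_cohort(spec)); after <- rnorm(3)
  expect_identical(before, after)

  expect_equal(nrow(a$subjects[[1]]$eeg$data), round(15 * 500))
  expect_equal(nrow(a$subjects[[1]]$fnirs$od_760$data), round(15 * 5.2083))
})

test_that("ground truth satisfies its invariants", {
  spec <- cohort_spec(12, seed = 3)
  ch <- generate_cohort(spec, signals = FALSE)
  expect_true(all(ch$truth$performance >= 0 & ch$truth$performance <= 100))
  for (m in names(ch$truth$latent[[1]])) {
    v <- ch$truth$latent[[5]][[m]]
    expect_equal(v, t(v))
    expect_equal(diag(v), rep(1, nrow(v)), ignore_attr = TRUE)
    expect_gte(min(eigen(v, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("planted edge-performance correlation converges to effect_r", {
  # large-n consistency on the ground-truth targets, per edge, averaged over
  # a few replicate cohorts to separate bias from sampling noise
  per_edge <- sapply(1:5, function(k) {
    ch <- generate_cohort(cohort_spec(200, effect_r = 0.8, seed = 12 + k),
                          signals = FALSE)
    apply(ch$truth$planted_edge_targets, 2, cor, y = ch$truth$performance)
  })
  expect_true(all(abs(rowMeans(per_edge) - 0.8) < 0.05))

  # moderate-n recovery, per edge, averaged over 50 replicates
  per_edge60 <- sapply(1:50, function(k) {
    ch <- generate_cohort(cohort_spec(60, effect_r = 0.8, seed = 5200 + k),
                          signals = FALSE)
    apply(ch$truth$planted_edge_targets, 2, cor, y = ch$truth$performance)
  })
  expect_true(all(abs(rowMeans(per_edge60) - 0.8) < 0.15))

  # under the null the planted correlations follow the null law of r;
  # oracle: direct simulation of independent normal pairs at the same n
  n <- 40
  obs <- unlist(lapply(1:60, function(k) {
    ch0 <- generate_cohort(cohort_spec(n, effect_r = 0, seed = 4000 + k),
                           signals = FALSE)
    apply(ch0$truth$planted_edge_targets, 2,
          cor, y = ch0$truth$performance)
  }))
  oracle <- neurocpm:::with_local_seed(77, {
    replicate(3000, cor(rnorm(n), rnorm(n)))
  })
  expect_lt(abs(mean(abs(obs)) - mean(abs(oracle))), 0.02)
  expect_lt(abs(sd(obs) - sd(oracle)), 0.03)
})

test_that("shared modulators plant AM connectivity in the EEG signals", {
  # weight ~1 edge, no noise: AM series of the planted pair nearly coincide
  spec <- cohort_spec(3, duration_s = 60, noise_sd = 0, effect_r = 0,
                      seed = 14)
  ch <- generate_cohort(spec)
  # a valid (positive semidefinite) matrix with a near-unit planted pair
  strong <- matrix(0.15, 8, 8); diag(strong) <- 1
  strong[1, 2] <- strong[2, 1] <- 0.999
  rec <- synthesize_eeg(list(beta_m_alpha = strong,
                             gamma_m_alpha = ch$truth$latent[[1]]$gamma_m_alpha),
                        spec)
  am <- amplitude_modulation(rec, "beta_m_alpha")
  cm <- pearson_connectivity(am)
  expect_gt(cm$values[1, 2], 0.99)

  # independent modulators at 300 s: |AM correlation| stays small
  spec0 <- cohort_spec(3, duration_s = 300, noise_sd = 0, effect_r = 0,
                       seed = 15)
  indep <- diag(8)
  rec0 <- synthesize_eeg(list(beta_m_alpha = indep, gamma_m_alpha = indep),
                         spec0)
  cm0 <- pearson_connectivity(amplitude_modulation(rec0, "beta_m_alpha"))
  off <- cm0$values[upper.tri(cm0$values)]
  expect_lt(max(abs(off)), 0.2)
})

test_that("fNIRS generator plants hemodynamic correlations and round-trips MBLL", {
  spec <- cohort_spec(3, duration_s = 300, noise_sd = 0, seed = 16)
  ch <- generate_cohort(spec)
  latent <- ch$truth$latent[[1]]
  strong <- matrix(0.25, 25, 25); diag(strong) <- 1
  strong[1, 2] <- strong[2, 1] <- 0.999
  hb_spec <- cohort_spec(3, duration_s = 300, noise_sd = 0, seed = 16,
                         fnirs_output = "hb")
  hb <- synthesize_fnirs(list(hbo = strong, hbr = latent$hbr), hb_spec)
  bp <- fnirs_bandpass(recording(hb$hbo, hb$fs))
  expect_gt(cor(bp$data[, 1], bp$data[, 2]), 0.99)

  # oxy/deoxy mutual correlation lands near the configured value
  spec2 <- cohort_spec(3, duration_s = 300, hbo_hbr_corr = -0.8, seed = 17,
                       fnirs_output = "hb")
  hb2 <- generate_cohort(spec2)$subjects[[1]]$fnirs
  cors <- sapply(seq_len(ncol(hb2$hbo)),
                 function(i) cor(hb2$hbo[, i], hb2$hbr[, i]))
  expect_lt(abs(mean(cors) - (-0.8)), 0.1)

  # forward-projected optical densities invert to the generator values
  od <- od_from_hb(hb)
  back <- mbll(od$od_760, od$od_850)
  expect_lt(max(abs(back$hbo - hb$hbo)) / max(abs(hb$hbo)), 1e-6)
  expect_lt(max(abs(back$hbr - hb$hbr)) / max(abs(hb$hbr)), 1e-6)
})

test_that("null cohorts drive LOSO prediction to chance level", {
  rs <- sapply(1:30, function(k) {
    pred_obs_r(loso_predict(latent_cohort(30, effect_r = 0, seed = 900 + k)))
  })
  expect_lt(abs(mean(rs)), 0.15)
})
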