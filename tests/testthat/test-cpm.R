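# Connectome-based predictive modelling: edge statistics, masks, CSS, LOSO.

test_that("edge-performance correlation matches cor.test edge by edge", {
  set.seed(21)
  n_subj <- 5; k <- 4
  mats <- lapply(1:n_subj, function(s) {
    connectivity_matrix(cor(matrix(rnorm(8 * k), 8, k)), "hbo")
  })
  perf <- c(10, 35, 52, 70, 91)
  st <- edge_performance_correlation(mats, perf)
  idx <- neurocpm:::edge_index(k)
  for (e in seq_len(nrow(idx))) {
    vals <- sapply(mats, function(m) m$values[idx[e, 1], idx[e, 2]])
    ct <- cor.test(vals, perf)
    expect_equal(st$r_matrix[idx[e, 1], idx[e, 2]], unname(ct$estimate),
                 tolerance = 1e-12)
    expect_equal(st$p_matrix[idx[e, 1], idx[e, 2]], ct$p.value,
                 tolerance = 1e-12)
  }

  # an edge identical to performance has r = 1 and vanishing p
  mats2 <- lapply(seq_len(n_subj), function(s) {
    v <- diag(3); v[1, 2] <- v[2, 1] <- perf[s] / 100; v[1, 3] <- v[3, 1] <- 0.1
    v[2, 3] <- v[3, 2] <- 0.1 + 0.001 * s
    connectivity_matrix(v, "hbo")
  })
  st2 <- edge_performance_correlation(mats2, perf)
  expect_equal(st2$r_matrix[1, 2], 1.0, tolerance = 1e-12)
  expect_lt(st2$p_matrix[1, 2], 1e-12)

  expect_error(edge_performance_correlation(mats, rep(50, n_subj)),
               "constant")
})

test_that("edge selection is calibrated under the null", {
  # permuted performances: fraction of edges with p <= 0.05 is ~0.05
  set.seed(22)
  hits <- 0; total <- 0
  for (b in 1:200) {
    E <- matrix(rnorm(20 * 10), 20, 10)
    perf <- rnorm(20)
    st <- neurocpm:::edge_stats_from_values(E, perf, 5)
    p <- st$p_matrix[upper.tri(st$p_matrix)]
    hits <- hits + sum(p <= 0.05); total <- total + length(p)
  }
  expect_lt(abs(hits / total - 0.05), 0.02)
})

test_that("build_mask applies the inclusive p <= alpha rule", {
  p <- matrix(1, 4, 4); diag(p) <- NA
  expect_equal(sum(build_mask(p)$mask), 0)

  p[1, 2] <- p[2, 1] <- 0.05          # exactly at threshold: selected
  p[3, 4] <- p[4, 3] <- 0.050001
  mk <- build_mask(p, alpha = 0.05)
  expect_true(mk$mask[1, 2])
  expect_false(mk$mask[3, 4])

  set.seed(23)
  pr <- matrix(runif(100), 10, 10); pr <- (pr + t(pr)) / 2; diag(pr) <- NA
  mk2 <- build_mask(pr, alpha = 0.3)
  idx <- neurocpm:::edge_index(10)
  brute <- sum(sapply(seq_len(nrow(idx)),
                      function(e) pr[idx[e, 1], idx[e, 2]] <= 0.3))
  expect_equal(sum(mk2$mask[idx]), brute)
  expect_error(build_mask(pr * 3, alpha = 0.05), "0, 1")
})

test_that("CSS is the signed sum over masked upper-triangle edges", {
  set.seed(24)
  v <- cor(matrix(rnorm(120), 20, 6))
  cm <- connectivity_matrix(v, "hbo")
  empty <- matrix(FALSE, 6, 6)
  expect_equal(css(cm, empty), 0)

  one <- empty; one[2, 5] <- one[5, 2] <- TRUE
  expect_equal(css(cm, one), v[2, 5])

  idx <- neurocpm:::edge_index(6)
  sel <- sample(nrow(idx), 10)
  mk <- empty
  for (e in sel) mk[idx[e, 1], idx[e, 2]] <- mk[idx[e, 2], idx[e, 1]] <- TRUE
  acc <- 0
  for (e in sel) acc <- acc + v[idx[e, 1], idx[e, 2]]
  expect_equal(css(cm, mk), acc, tolerance = 1e-12)

  expect_error(css(cm, matrix(FALSE, 5, 5)), "shape")
})

test_that("mae is the mean and sd of absolute errors", {
  expect_equal(mae(c(1, 2, 3), c(1, 2, 3)), list(mean = 0, sd = 0))
  expect_equal(mae(c(50, 60), c(40, 80))$mean, 15)
  set.seed(25)
  a <- runif(40, 0, 100); b <- runif(40, 0, 100)
  m <- mae(a, b)
  acc <- c()
  for (i in seq_along(a)) acc <- c(acc, abs(a[i] - b[i]))
  expect_equal(m$mean, mean(acc), tolerance = 1e-12)
  expect_equal(m$sd, sd(acc), tolerance = 1e-12)
  expect_error(mae(1:3, 1:4), "length")
})

test_that("LOSO prediction has no leakage and one fold per subject", {
  tab <- latent_cohort(10, effect_r = 0.6, seed = 31)
  rep <- loso_predict(tab)
  expect_equal(nrow(rep$predictions), 10)
  expect_equal(rep$predictions$subject, tab$subjects)
  expect_equal(length(rep$fold_masks), 10)
  expect_equal(rep$mae$mean,
               mean(abs(rep$predictions$predicted - rep$predictions$observed)))

  # leakage audit: recompute fold 4 from a cohort with subject 4 deleted
  s <- 4
  keep <- setdiff(seq_len(10), s)
  tab_wo <- cohort_table(tab$matrices[keep], tab$performance[keep])
  for (m in tab$modalities) {
    st <- edge_performance_correlation(tab_wo, tab_wo$performance,
                                       modality = m)
    expect_identical(st$p_matrix, rep$fold_masks[[s]][[m]]$p_matrix)
    expect_identical(st$r_matrix, rep$fold_masks[[s]][[m]]$r_matrix)
    mk <- build_mask(st, alpha = rep$alpha)
    expect_identical(mk$mask, rep$fold_masks[[s]][[m]]$mask)
  }
  # and the fold's prediction is reproduced from training data alone
  Xtr <- sapply(tab$modalities, function(m) {
    sapply(keep, function(i) css(tab$matrices[[i]][[m]],
                                 rep$fold_masks[[s]][[m]]))
  })
  xte <- t(sapply(tab$modalities, function(m) {
    css(tab$matrices[[s]][[m]], rep$fold_masks[[s]][[m]])
  }))
  z <- neurocpm:::zscore_fit(Xtr)
  fit <- neurocpm:::fit_fold_svr(neurocpm:::zscore_apply(Xtr, z),
                                 tab$performance[keep], rep$svr)
  expect_equal(as.numeric(predict(fit, neurocpm:::zscore_apply(xte, z))),
               rep$predictions$predicted[s], tolerance = 1e-12)
})

test_that("alpha = 1 saturates the mask and CSS becomes the full edge sum", {
  tab <- latent_cohort(8, effect_r = 0.4, seed = 32)
  rep <- loso_predict(tab, alpha = 1)
  for (m in tab$modalities) {
    mk <- rep$fold_masks[[1]][[m]]$mask
    expect_true(all(mk[upper.tri(mk)]))
  }
  v <- tab$matrices[[2]]$hbo$values
  expect_equal(css(tab$matrices[[2]]$hbo, rep$fold_masks[[1]]$hbo),
               sum(v[upper.tri(v)]), tolerance = 1e-12)
})

test_that("empty masks yield a model that ignores the connectivity values", {
  # identical matrices across subjects: every edge has zero variance, no edge
  # is ever selected, so predictions depend only on the training performances
  base <- latent_cohort(8, effect_r = 0, seed = 33)
  perf <- base$performance
  fixed1 <- lapply(base$matrices[[1]], identity)
  mats1 <- stats::setNames(rep(list(fixed1), 8), base$subjects)
  fixed2 <- lapply(base$matrices[[2]], identity)
  mats2 <- stats::setNames(rep(list(fixed2), 8), base$subjects)
  r1 <- loso_predict(cohort_table(mats1, perf))
  r2 <- loso_predict(cohort_table(mats2, perf))
  expect_equal(sum(sapply(r1$fold_masks[[1]], function(m) sum(m$mask))), 0)
  expect_equal(r1$predictions$predicted, r2$predictions$predicted,
               tolerance = 1e-10)

  expect_error(loso_predict(cohort_table(mats1[1:3], perf[1:3])),
               "at least 4")
})
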