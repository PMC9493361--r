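# Connectome-based predictive modelling: LOSO edge selection, connectivity
# summary scores (CSS), linear SVR, out-of-fold prediction.

#' Cohort table
#'
#' Per-subject bundle of the four connectivity matrices (hbo, hbr,
#' beta_m_alpha, gamma_m_alpha) plus the scalar performance score (0-100 %).
#'
#' @param matrices named list (by subject id) of named lists of
#'   [connectivity_matrix()] objects, one per modality.
#' @param performance numeric vector of performance percentages, one per
#'   subject, same order as `matrices`.
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(matrices, performance) {
  if (length(matrices) != length(performance)) {
    stop("one performance value per subject is required", call. = FALSE)
  }
  ids <- names(matrices)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_along(matrices))
  mods <- names(matrices[[1]])
  for (s in seq_along(matrices)) {
    if (!identical(sort(names(matrices[[s]])), sort(mods))) {
      stop("all subjects must carry the same modalities", call. = FALSE)
    }
  }
  for (m in mods) {
    dims <- vapply(matrices, function(x) nrow(x[[m]]$values), integer(1))
    if (length(unique(dims)) != 1) {
      stop(sprintf("inconsistent channel count across subjects for %s", m),
           call. = FALSE)
    }
  }
  if (any(!is.finite(performance)) || any(performance < 0 | performance > 100)) {
    stop("performance scores must be finite percentages in [0, 100]",
         call. = FALSE)
  }
  structure(list(subjects = ids, modalities = mods, matrices = matrices,
                 performance = as.numeric(performance)),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, modalities: %s\n",
              length(x$subjects), paste(x$modalities, collapse = ", ")))
  invisible(x)
}

# n_subjects x n_edges matrix of canonical edge values for one modality
edge_value_matrix <- function(cohort, modality, subjects = NULL) {
  if (is.null(subjects)) subjects <- seq_along(cohort$subjects)
  mats <- lapply(cohort$matrices[subjects], function(x) x[[modality]]$values)
  n <- nrow(mats[[1]])
  idx <- edge_index(n)
  t(vapply(mats, function(v) v[idx], numeric(nrow(idx))))
}

#' Edge-wise correlation with performance
#'
#' For every edge, the Pearson correlation (and its two-tailed p-value from
#' the t distribution) between the edge's connectivity values across training
#' subjects and their performance scores. Edges with zero variance across
#' subjects get `NA` (and are never selected by [build_mask()]).
#'
#' @param matrices list of [connectivity_matrix()] objects (one per training
#'   subject, same modality), or a `cohort_table` together with `modality`.
#' @param performances numeric vector of performance scores (non-constant).
#' @param modality required when `matrices` is a `cohort_table`.
#' @return list with symmetric `r_matrix` and `p_matrix` (diagonal `NA`).
#' @export
edge_performance_correlation <- function(matrices, performances,
                                         modality = NULL) {
  if (inherits(matrices, "cohort_table")) {
    stopifnot(!is.null(modality))
    E <- edge_value_matrix(matrices, modality)
  } else {
    vals <- lapply(matrices, function(x) {
      if (inherits(x, "connectivity_matrix")) x$values else as.matrix(x)
    })
    n <- nrow(vals[[1]])
    idx <- edge_index(n)
    E <- t(vapply(vals, function(v) v[idx], numeric(nrow(idx))))
  }
  ns <- nrow(E)
  if (ns < 3) stop("need at least 3 training subjects", call. = FALSE)
  if (length(performances) != ns) {
    stop("one performance value per training subject is required", call. = FALSE)
  }
  if (sd(performances) == 0) {
    stop("training performances are constant: correlation undefined",
         call. = FALSE)
  }
  sds <- apply(E, 2, sd)
  r <- rep(NA_real_, ncol(E))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(cor(E[, ok, drop = FALSE], performances))
  df <- ns - 2
  p <- rep(NA_real_, length(r))
  finite_r <- ok & abs(r) < 1
  p[finite_r] <- 2 * pt(-abs(r[finite_r]) * sqrt(df / (1 - r[finite_r]^2)), df)
  p[ok & abs(r) >= 1] <- 0
  nch <- (1 + sqrt(1 + 8 * ncol(E))) / 2
  r_m <- edges_to_matrix(r, nch); diag(r_m) <- NA_real_
  p_m <- edges_to_matrix(p, nch); diag(p_m) <- NA_real_
  list(r_matrix = r_m, p_matrix = p_m)
}

#' Build an edge-selection mask
#'
#' Selects edges with `p <= alpha` (inclusive threshold). `NA` p-values
#' (zero-variance edges) are never selected.
#'
#' @param stats output of [edge_performance_correlation()], or a p-value
#'   matrix.
#' @param alpha significance level, default 0.05.
#' @param fold_id optional identifier of the left-out subject.
#' @return object of class `edge_mask` with fields `mask` (logical matrix),
#'   `r_matrix`, `p_matrix`, `alpha`, `fold_id`.
#' @export
build_mask <- function(stats, alpha = 0.05, fold_id = NA) {
  if (is.matrix(stats)) stats <- list(r_matrix = NULL, p_matrix = stats)
  p <- stats$p_matrix
  pv <- p[!is.na(p)]
  if (length(pv) && (min(pv) < 0 || max(pv) > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  mask <- !is.na(p) & p <= alpha
  diag(mask) <- FALSE
  mask <- mask | t(mask)
  structure(list(mask = mask, r_matrix = stats$r_matrix, p_matrix = p,
                 alpha = alpha, fold_id = fold_id),
            class = "edge_mask")
}

#' @export
print.edge_mask <- function(x, ...) {
  cat(sprintf("<edge_mask> %d / %d edges selected (alpha = %g%s)\n",
              sum(x$mask[upper.tri(x$mask)]),
              sum(upper.tri(x$mask)), x$alpha,
              if (!is.na(x$fold_id[1])) paste0(", fold ", x$fold_id) else ""))
  invisible(x)
}

#' Connectivity summary score
#'
#' Sum of a subject's signed connectivity values over the masked edges
#' (strict upper triangle). An empty mask gives 0.
#'
#' @param m a [connectivity_matrix()] (or square matrix).
#' @param mask an [build_mask()] result, or a logical matrix.
#' @return scalar CSS.
#' @export
css <- function(m, mask) {
  v <- if (inherits(m, "connectivity_matrix")) m$values else as.matrix(m)
  mk <- if (inherits(mask, "edge_mask")) mask$mask else mask
  if (!identical(dim(v), dim(mk))) {
    stop("mask and matrix shapes disagree", call. = FALSE)
  }
  sum(v[mk & upper.tri(mk)])
}

#' Linear SVR hyperparameters
#'
#' @param C box constraint, default 1.
#' @param epsilon_frac the epsilon tube is `epsilon_frac` times the standard
#'   deviation of the training performances; default 0.1 (one tenth).
#' @return object of class `svr_spec`.
#' @export
svr_spec <- function(C = 1, epsilon_frac = 0.1) {
  if (C <= 0) stop("C must be > 0", call. = FALSE)
  if (epsilon_frac < 0) stop("epsilon fraction must be >= 0", call. = FALSE)
  structure(list(C = C, epsilon_frac = epsilon_frac), class = "svr_spec")
}

# z-score columns with training statistics; zero-variance columns pass
# through unscaled (they carry no information either way)
zscore_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[s == 0] <- 1
  list(mu = mu, s = s)
}
zscore_apply <- function(X, z) sweep(sweep(X, 2, z$mu), 2, z$s, `/`)

fit_fold_svr <- function(Xtr, ytr, spec) {
  eps <- spec$epsilon_frac * sd(ytr)
  e1071::svm(x = Xtr, y = ytr, type = "eps-regression", kernel = "linear",
             cost = spec$C, epsilon = eps, scale = FALSE)
}

#' Leave-one-subject-out connectome-based prediction
#'
#' For each left-out subject: edge-performance correlations and the
#' `p <= alpha` mask are computed on the training subjects only,
#' independently per modality; every training subject is summarised into four
#' CSS features (one per modality); features are z-scored with training-fold
#' statistics; a linear epsilon-SVR (C and epsilon per `svr`) is fitted on
#' the training features; the left-out subject's CSS vector (using the
#' training fold's masks) is then predicted. The left-out subject never
#' contributes to mask selection, feature scaling or model fitting.
#'
#' @param cohort a [cohort_table()] with at least 4 subjects.
#' @param alpha edge-selection significance level (default 0.05, inclusive).
#' @param svr an [svr_spec()].
#' @param clip logical: clip predictions into \[0, 100\] (default `FALSE`;
#'   raw regressor output is reported).
#' @return object of class `prediction_report`: data.frame `predictions`
#'   (subject, observed, predicted, abs_error), `mae` (mean and sd of the
#'   absolute errors, percentage scale), and `fold_masks` (per fold, one
#'   [build_mask()] result per modality, for downstream union masks).
#' @export
loso_predict <- function(cohort, alpha = 0.05, svr = svr_spec(),
                         clip = FALSE) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- length(cohort$subjects)
  if (n < 4) stop("LOSO prediction needs at least 4 subjects", call. = FALSE)
  y <- cohort$performance
  mods <- cohort$modalities
  edge_cache <- lapply(mods, function(m) edge_value_matrix(cohort, m))
  names(edge_cache) <- mods
  nch <- vapply(mods, function(m) {
    nrow(cohort$matrices[[1]][[m]]$values)
  }, integer(1))

  predicted <- numeric(n)
  fold_masks <- vector("list", n)
  for (s in seq_len(n)) {
    train <- setdiff(seq_len(n), s)
    if (sd(y[train]) == 0) {
      stop(sprintf("fold %s: training performances are constant",
                   cohort$subjects[s]), call. = FALSE)
    }
    masks <- list()
    Xtr <- matrix(0, length(train), length(mods),
                  dimnames = list(NULL, mods))
    xte <- matrix(0, 1, length(mods), dimnames = list(NULL, mods))
    for (m in mods) {
      E <- edge_cache[[m]]
      st <- edge_stats_from_values(E[train, , drop = FALSE], y[train], nch[[m]])
      mk <- build_mask(st, alpha = alpha, fold_id = cohort$subjects[s])
      masks[[m]] <- mk
      sel <- mk$mask[edge_index(nch[[m]])]
      Xtr[, m] <- rowSums(E[train, sel, drop = FALSE])
      xte[, m] <- sum(E[s, sel])
    }
    z <- zscore_fit(Xtr)
    fit <- fit_fold_svr(zscore_apply(Xtr, z), y[train], svr)
    predicted[s] <- as.numeric(predict(fit, zscore_apply(xte, z)))
    fold_masks[[s]] <- masks
  }
  if (clip) predicted <- pmin(100, pmax(0, predicted))
  abs_err <- abs(predicted - y)
  report <- list(
    predictions = data.frame(subject = cohort$subjects, observed = y,
                             predicted = predicted, abs_error = abs_err,
                             stringsAsFactors = FALSE),
    mae = mae(predicted, y),
    alpha = alpha, svr = svr, clip = clip,
    fold_masks = stats::setNames(fold_masks, cohort$subjects)
  )
  class(report) <- "prediction_report"
  report
}

# edge_performance_correlation working directly on a precomputed edge-value
# matrix (internal fast path used by loso_predict; identical maths)
edge_stats_from_values <- function(E, performances, nch) {
  ns <- nrow(E)
  sds <- apply(E, 2, sd)
  r <- rep(NA_real_, ncol(E))
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.numeric(cor(E[, ok, drop = FALSE], performances))
  df <- ns - 2
  p <- rep(NA_real_, length(r))
  finite_r <- ok & abs(r) < 1
  p[finite_r] <- 2 * pt(-abs(r[finite_r]) * sqrt(df / (1 - r[finite_r]^2)), df)
  p[ok & abs(r) >= 1] <- 0
  r_m <- edges_to_matrix(r, nch); diag(r_m) <- NA_real_
  p_m <- edges_to_matrix(p, nch); diag(p_m) <- NA_real_
  list(r_matrix = r_m, p_matrix = p_m)
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d subjects, MAE %.2f +/- %.2f %%\n",
              nrow(x$predictions), x$mae$mean, x$mae$sd))
  invisible(x)
}

#' Mean absolute error of performance predictions
#'
#' @param predicted,observed numeric vectors of equal length (percentages).
#' @return list with `mean` and `sd` of the per-subject absolute errors, on
#'   the percentage scale.
#' @export
mae <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("predicted and observed lengths differ", call. = FALSE)
  }
  if (length(predicted) < 1) stop("need at least one pair", call. = FALSE)
  e <- abs(predicted - observed)
  list(mean = mean(e), sd = if (length(e) > 1) sd(e) else 0)
}
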