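# Cross-modality coupling on CSS vectors built from union-of-LOSO masks,
# with permutation inference and Benjamini-Hochberg FDR correction.

#' Union of LOSO fold masks
#'
#' Element-wise OR of the per-fold edge masks of one modality: an edge is in
#' the union if it was selected in at least one LOSO iteration. Provenance
#' (which folds selected each edge) is retained.
#'
#' @param fold_masks list of [build_mask()] results sharing a shape.
#' @return object of class `union_mask` with fields `mask` (logical matrix),
#'   `count` (per-edge number of selecting folds) and `provenance` (named
#'   list, edge `"i-j"` -> fold ids).
#' @export
union_mask <- function(fold_masks) {
  stopifnot(length(fold_masks) >= 1)
  masks <- lapply(fold_masks, function(x) {
    if (inherits(x, "edge_mask")) x$mask else as.matrix(x)
  })
  dims <- vapply(masks, dim, integer(2))
  if (any(dims != dims[, 1])) stop("fold masks differ in shape", call. = FALSE)
  cnt <- Reduce(`+`, masks)
  mk <- cnt > 0
  diag(mk) <- FALSE
  idx <- edge_index(nrow(mk))
  sel <- which(mk[idx])
  prov <- lapply(sel, function(e) {
    ij <- idx[e, ]
    ids <- vapply(seq_along(fold_masks), function(f) {
      if (!masks[[f]][ij[1], ij[2]]) return(NA_character_)
      fm <- fold_masks[[f]]
      id <- if (inherits(fm, "edge_mask")) fm$fold_id else f
      as.character(id)
    }, character(1))
    ids[!is.na(ids)]
  })
  names(prov) <- paste(idx[sel, 1], idx[sel, 2], sep = "-")
  structure(list(mask = mk, count = cnt, provenance = prov),
            class = "union_mask")
}

#' @export
print.union_mask <- function(x, ...) {
  cat(sprintf("<union_mask> %d / %d edges selected in >= 1 fold\n",
              sum(x$mask[upper.tri(x$mask)]), sum(upper.tri(x$mask))))
  invisible(x)
}

#' Per-modality CSS vectors under the union masks
#'
#' Computes, for every subject of the cohort (no fold exclusion at this
#' stage), the CSS under each modality's union mask.
#'
#' @param cohort a [cohort_table()].
#' @param union_masks named list (by modality) of [union_mask()] objects (or
#'   logical matrices).
#' @return named list of per-subject numeric vectors, one per modality.
#' @export
css_vectors <- function(cohort, union_masks) {
  stopifnot(inherits(cohort, "cohort_table"))
  missing <- setdiff(cohort$modalities, names(union_masks))
  if (length(missing)) {
    stop(sprintf("missing union mask for modality: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- lapply(cohort$modalities, function(m) {
    mk <- union_masks[[m]]
    mk <- if (inherits(mk, "union_mask")) mk$mask else as.matrix(mk)
    vapply(cohort$matrices, function(x) css(x[[m]], mk), numeric(1))
  })
  stats::setNames(out, cohort$modalities)
}

#' Permutation test for a Pearson correlation
#'
#' The observed statistic is the Pearson correlation of `x` and `y`; the null
#' distribution is built by permuting `y` across subjects. The two-tailed
#' p-value uses the add-one estimator
#' `p = (1 + #permutations with |r| >= |r_obs|) / (1 + n_perm)`, which is
#' never zero. Seeded and reproducible.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @param n_perm number of permutations (>= 100); default 10000. The
#'   method-faithful preset is 1e6.
#' @param seed optional integer seed.
#' @return list with `r` (observed), `p`, `n_perm`.
#' @export
permutation_corr_test <- function(x, y, n_perm = 10000, seed = NULL) {
  n <- length(x)
  if (length(y) != n || n < 3) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  r_obs <- cor(x, y)
  xs <- (x - mean(x)) / sd(x)
  ys <- (y - mean(y)) / sd(y)
  run <- function() {
    exceed <- 0L
    chunk <- 10000L
    done <- 0L
    while (done < n_perm) {
      m <- min(chunk, n_perm - done)
      idx <- vapply(seq_len(m), function(i) sample.int(n), integer(n))
      rp <- as.numeric(crossprod(xs, matrix(ys[idx], n)) / (n - 1))
      exceed <- exceed + sum(abs(rp) >= abs(r_obs) - 1e-12)
      done <- done + m
    }
    exceed
  }
  exceed <- if (is.null(seed)) run() else with_local_seed(seed, run())
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values with enforced monotonicity, via
#' `p.adjust(method = "BH")`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
fdr_correct <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

# the six CSS comparisons, fixed order: two intra-modality then four
# inter-modality pairs
coupling_pairs <- function() {
  rbind(c("hbo", "hbr"),
        c("beta_m_alpha", "gamma_m_alpha"),
        c("hbo", "beta_m_alpha"),
        c("hbo", "gamma_m_alpha"),
        c("hbr", "beta_m_alpha"),
        c("hbr", "gamma_m_alpha"))
}

#' Cross-modality CSS coupling analysis
#'
#' Builds the union-of-folds mask per modality, computes every subject's CSS
#' vector under it, and tests the six pairwise Pearson correlations
#' (hbo-hbr, beta-gamma, and the four inter-modality pairs) with a
#' permutation test, correcting the six p-values with Benjamini-Hochberg FDR.
#'
#' @param cohort a [cohort_table()].
#' @param fold_masks the `fold_masks` field of a [loso_predict()] report
#'   (list per fold of per-modality [build_mask()] results).
#' @param n_perm permutations per comparison (default 10000; the
#'   method-faithful preset is 1e6).
#' @param seed integer seed for the permutation draws.
#' @return object of class `coupling_report`: data.frame `comparisons`
#'   (pair, r, p, q, n_perm), `css` (per-modality CSS vectors) and
#'   `union_masks`.
#' @export
coupling_analysis <- function(cohort, fold_masks, n_perm = 10000,
                              seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  mods <- cohort$modalities
  um <- lapply(mods, function(m) {
    union_mask(lapply(fold_masks, function(fm) fm[[m]]))
  })
  names(um) <- mods
  vecs <- css_vectors(cohort, um)
  pairs <- coupling_pairs()
  res <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- vecs[[pairs[k, 1]]]
    b <- vecs[[pairs[k, 2]]]
    if (sd(a) == 0 || sd(b) == 0) {
      res[[k]] <- list(r = NA_real_, p = NA_real_, n_perm = n_perm)
    } else {
      res[[k]] <- permutation_corr_test(
        a, b, n_perm = n_perm,
        seed = if (is.null(seed)) NULL else seed + k)
    }
  }
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- rep(NA_real_, length(p))
  if (all(is.finite(p))) q <- fdr_correct(p)
  comparisons <- data.frame(
    modality_a = pairs[, 1], modality_b = pairs[, 2],
    r = vapply(res, `[[`, numeric(1), "r"),
    p = p, q = q, n_perm = n_perm, stringsAsFactors = FALSE)
  structure(list(comparisons = comparisons, css = vecs, union_masks = um),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat("<coupling_report>\n")
  print(x$comparisons, digits = 3)
  invisible(x)
}
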