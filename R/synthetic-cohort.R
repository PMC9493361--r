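# Synthetic cohort generator: paired EEG-like and fNIRS-like recordings plus
# a performance score, with known, controllable ground truth.

#' Default planted predictive edges
#'
#' Three edges per hemodynamic modality and one per EEG amplitude-modulation
#' modality (EEG masks are the sparser ones in practice).
#'
#' @return data.frame with columns `modality`, `i`, `j`.
#' @export
default_predictive_edges <- function() {
  data.frame(
    modality = c("hbo", "hbo", "hbo", "hbr", "hbr", "hbr",
                 "beta_m_alpha", "gamma_m_alpha"),
    i = c(1, 3, 5, 7, 9, 11, 1, 3),
    j = c(2, 4, 6, 8, 10, 12, 2, 4),
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort specification
#'
#' Defines the acquisition geometry and the planted ground truth of a
#' simulated resting-state cohort: 8-channel EEG at 500 Hz and 25-channel
#' fNIRS at 5.2083 Hz, 300 s (5 min) of eyes-open rest, and a set of
#' connectivity edges whose strength is linearly tied to the behavioural
#' performance score with target correlation `effect_r`.
#'
#' @param n_subjects number of subjects (>= 3).
#' @param duration_s record duration in seconds (default 300).
#' @param eeg_channels,fnirs_channels channel counts (defaults 8 and 25).
#' @param eeg_fs,fnirs_fs sampling rates in Hz (defaults 500 and 5.2083).
#' @param predictive_edges data.frame (`modality`, `i`, `j`) of planted
#'   edges; default [default_predictive_edges()].
#' @param effect_r target edge-performance correlation in \[-1, 1\]
#'   (default 0.8).
#' @param noise_sd additive noise amplitude relative to the unit-scale signal
#'   components (default 0.2).
#' @param hbo_hbr_corr mutual oxy/deoxy correlation (default -0.8).
#' @param eeg_band_corr shared-modulator correlation between the beta and
#'   gamma envelope modulators (default 0.3; both bands ride the same
#'   alpha-range modulation).
#' @param hbo_gamma_coupling loading of a shared latent linking the planted
#'   hbo and gamma-m-alpha edge weights beyond their common performance
#'   component (default 0.4); capped at `sqrt(1 - effect_r^2)`.
#' @param fnirs_output `"od"` (two-wavelength optical densities, the default,
#'   so the MBLL inversion is exercised) or `"hb"` (hemoglobin directly).
#' @param artifacts logical: inject ocular-like transients and high-amplitude
#'   spikes into the EEG (off by default; used to test wICA).
#' @param seed integer seed; the whole cohort is reproducible from
#'   (spec, seed).
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, duration_s = 300, eeg_channels = 8,
                        fnirs_channels = 25, eeg_fs = 500,
                        fnirs_fs = 5.2083,
                        predictive_edges = default_predictive_edges(),
                        effect_r = 0.8, noise_sd = 0.2,
                        hbo_hbr_corr = -0.8, eeg_band_corr = 0.3,
                        hbo_gamma_coupling = 0.4,
                        fnirs_output = c("od", "hb"),
                        artifacts = FALSE, seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 3) {
    stop("`n_subjects` must be >= 3", call. = FALSE)
  }
  if (duration_s <= 0) stop("`duration_s` must be > 0", call. = FALSE)
  if (abs(effect_r) > 1) stop("`effect_r` must lie in [-1, 1]", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (abs(hbo_hbr_corr) >= 1) {
    stop("`hbo_hbr_corr` must lie in (-1, 1)", call. = FALSE)
  }
  pe <- predictive_edges
  stopifnot(all(c("modality", "i", "j") %in% names(pe)))
  nch <- c(hbo = fnirs_channels, hbr = fnirs_channels,
           beta_m_alpha = eeg_channels, gamma_m_alpha = eeg_channels)
  bad <- !pe$modality %in% names(nch)
  if (any(bad)) {
    stop(sprintf("`predictive_edges`: unknown modality '%s'",
                 pe$modality[bad][1]), call. = FALSE)
  }
  over <- pe$i >= pe$j | pe$i < 1 | pe$j > nch[pe$modality]
  if (any(over)) {
    stop("`predictive_edges`: edge indices must satisfy 1 <= i < j <= channel count",
         call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects), duration_s = duration_s,
    eeg_channels = as.integer(eeg_channels),
    fnirs_channels = as.integer(fnirs_channels),
    eeg_fs = eeg_fs, fnirs_fs = fnirs_fs,
    predictive_edges = pe, effect_r = effect_r, noise_sd = noise_sd,
    hbo_hbr_corr = hbo_hbr_corr, eeg_band_corr = eeg_band_corr,
    hbo_gamma_coupling = min(hbo_gamma_coupling,
                             sqrt(max(0, 1 - effect_r^2))),
    fnirs_output = match.arg(fnirs_output),
    artifacts = isTRUE(artifacts), seed = as.integer(seed)
  ), class = "cohort_spec")
}

# baseline connectivity and planted-edge mapping constants
SYNTH_BASELINE <- c(hbo = 0.25, hbr = 0.25,
                    beta_m_alpha = 0.15, gamma_m_alpha = 0.15)
SYNTH_EDGE_JITTER_SD <- 0.05    # subject-to-subject spread of null edges
SYNTH_EDGE_BASE <- 0.30         # planted-edge mean connectivity
SYNTH_EDGE_GAIN <- 0.15         # connectivity units per unit latent weight
SYNTH_MOD_DEPTH <- 0.4          # EEG envelope modulation depth
SYNTH_HBO_AMP <- 0.5            # uM, sd of HbO slow fluctuations
SYNTH_HBR_AMP <- 0.25           # uM, sd of HbR slow fluctuations

# block mixing matrix for two coupled channel sets: X = E %*% t(M) with
# orthonormal E has crossprod [[Ra, rho*A*B], [rho*B*A, Rb]] where A, B are
# the symmetric square roots of Ra, Rb. Positive semidefinite by
# construction, so planted within-block values are realised exactly.
coupled_block_mixing <- function(Ra, Rb, rho) {
  k <- nrow(Ra)
  A <- sqrtm_psd(Ra)
  B <- sqrtm_psd(Rb)
  rbind(cbind(A, matrix(0, k, k)),
        cbind(rho * B, sqrt(1 - rho^2) * B))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject performance scores (a clipped linear transform of a
#' standard-normal latent, location 70, scale 24.18, bounded to \[0, 100\]),
#' plants edge-performance correlations of exactly `effect_r` at the chosen
#' edges (by construction in the sample, not just in expectation), builds
#' per-subject latent connectivity matrices, and optionally renders them into
#' EEG and fNIRS signals via [synthesize_eeg()] and [synthesize_fnirs()].
#'
#' @param spec a [cohort_spec()].
#' @param signals logical: render full multichannel recordings (`TRUE`,
#'   default) or return only latent matrices and ground truth (`FALSE`,
#'   orders of magnitude faster; used for statistical replicate studies).
#' @return object of class `synthetic_cohort`: `subjects` (per subject: `id`,
#'   `performance`, and with `signals = TRUE` an `eeg` [recording()] plus
#'   `fnirs` data per `spec$fnirs_output`), and `truth` (a `ground_truth`
#'   object: `performance`, `planted_edge_targets` matrix, `latent`
#'   per-subject per-modality correlation matrices).
#' @export
generate_cohort <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, generate_cohort_impl(spec, signals))
}

generate_cohort_impl <- function(spec, signals) {
  n <- spec$n_subjects
  pe <- spec$predictive_edges

  z <- rnorm(n)
  perf <- pmin(100, pmax(0, 70 + 24.18 * z))
  if (sd(perf) == 0) perf[1] <- max(0, perf[1] - 1)  # pathological tiny-n draw
  p_std <- as.numeric(scale(perf))

  # shared latent coupling the planted hbo and gamma edges over and above
  # their common performance component
  u <- rnorm(n)

  # planted weights are correlated with performance in expectation, so a
  # finite cohort shows the natural sampling fluctuation of Pearson's r
  # around effect_r (and exactly the null law of r when effect_r = 0)
  r <- spec$effect_r
  n_edges <- nrow(pe)
  W <- matrix(0, n, n_edges)
  for (e in seq_len(n_edges)) {
    a <- if (pe$modality[e] %in% c("hbo", "gamma_m_alpha")) {
      spec$hbo_gamma_coupling
    } else 0
    c2 <- max(0, 1 - r^2 - a^2)
    W[, e] <- r * p_std + a * u + sqrt(c2) * rnorm(n)
  }
  targets <- SYNTH_EDGE_BASE + SYNTH_EDGE_GAIN * W
  targets[targets > 0.85] <- 0.85
  targets[targets < -0.85] <- -0.85

  nch <- c(hbo = spec$fnirs_channels, hbr = spec$fnirs_channels,
           beta_m_alpha = spec$eeg_channels,
           gamma_m_alpha = spec$eeg_channels)
  # null-edge jitter drawn once per modality as subject x edge matrices
  jitter <- lapply(names(nch), function(m) {
    ne <- nch[[m]] * (nch[[m]] - 1) / 2
    SYNTH_BASELINE[[m]] + SYNTH_EDGE_JITTER_SD * matrix(rnorm(n * ne), n, ne)
  })
  names(jitter) <- names(nch)

  latent <- vector("list", n)
  for (s in seq_len(n)) {
    latent[[s]] <- lapply(names(nch), function(m) {
      k <- nch[[m]]
      vals <- jitter[[m]][s, ]
      sel <- which(pe$modality == m)
      if (length(sel)) {
        idx <- edge_index(k)
        pos <- match(paste(pe$i[sel], pe$j[sel]),
                     paste(idx[, 1], idx[, 2]))
        vals[pos] <- targets[s, sel]
      }
      nearest_correlation(edges_to_matrix(vals, k))
    })
    names(latent[[s]]) <- names(nch)
  }

  truth <- structure(list(
    performance = perf,
    planted_edges = pe,
    planted_edge_targets = targets,
    latent = latent
  ), class = "ground_truth")

  subjects <- vector("list", n)
  for (s in seq_len(n)) {
    subj <- list(id = sprintf("S%02d", s), performance = perf[s])
    if (signals) {
      subj$eeg <- synthesize_eeg(latent[[s]], spec)
      subj$fnirs <- synthesize_fnirs(latent[[s]], spec)
    }
    subjects[[s]] <- subj
  }
  names(subjects) <- vapply(subjects, `[[`, character(1), "id")
  structure(list(subjects = subjects, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, effect_r = %g, seed = %d\n",
              length(x$subjects), x$spec$effect_r, x$spec$seed))
  invisible(x)
}

# band-limited unit-sd latent signals with an exact sample correlation
# structure: white noise -> FIR band-pass -> centre -> QR orthonormalise ->
# mix with the symmetric square root of the target correlation matrix
correlated_band_latents <- function(n_time, mixing, f_low, f_high, fs) {
  q <- nrow(mixing)
  if (n_time <= q) {
    stop("record too short for the requested channel count", call. = FALSE)
  }
  E <- matrix(rnorm(n_time * q), n_time, q)
  h <- fir_bandpass(f_low, f_high, fs,
                    order = min(500, 2 * floor((n_time - 1) / 2)))
  E <- fir_filter_zerophase(E, h)
  E <- sweep(E, 2, colMeans(E))
  Q <- qr.Q(qr(E))
  L <- Q %*% t(mixing)
  L * sqrt(n_time - 1)
}

#' Synthesize one subject's EEG recording
#'
#' Each channel is the sum of a beta-band and a gamma-band sinusoidal carrier
#' (frequencies drawn per channel inside each band) whose instantaneous
#' amplitudes carry alpha-range (8-12 Hz) modulators, plus broadband noise.
#' The modulators are mixed so their pairwise correlations reproduce the
#' subject's latent beta-m-alpha and gamma-m-alpha connectivity matrices:
#' shared modulation, not phase coupling, is the connectivity mechanism, so
#' the amplitude-modulation ground truth is well defined.
#'
#' Consumes the current RNG stream; [generate_cohort()] seeds it.
#'
#' @param latent named list with `beta_m_alpha` and `gamma_m_alpha` target
#'   correlation matrices (channels x channels).
#' @param spec a [cohort_spec()] (`eeg_fs` must be at least twice the highest
#'   synthesized frequency).
#' @return an `eeg` [recording()].
#' @export
synthesize_eeg <- function(latent, spec) {
  fs <- spec$eeg_fs
  if (fs < 2 * 50) stop("eeg_fs must be >= 100 Hz", call. = FALSE)
  k <- spec$eeg_channels
  n_time <- round(spec$duration_s * fs)
  mix <- coupled_block_mixing(latent$beta_m_alpha, latent$gamma_m_alpha,
                              spec$eeg_band_corr)
  M <- correlated_band_latents(n_time, mix, 8, 12, fs)
  t <- (seq_len(n_time) - 1) / fs
  # common carrier frequencies, random phase per channel. Two constraints:
  # (1) the carrier bands are too narrow to hold both 8-12 Hz modulation
  # sidebands, so envelope extraction applies a linear distortion; a shared
  # frequency keeps that distortion identical across channels and the AM
  # correlation equal to the planted modulator correlation. (2) carriers sit
  # so that neither band's sidebands fall inside the other band
  # (17 +/- 8..12 -> 5..9 / 25..29 Hz; 45 +/- 8..12 -> 33..37 / 53..57 Hz),
  # otherwise cross-band leakage beats against the in-band carrier and
  # corrupts its envelope.
  fb <- rep(17, k)
  fg <- rep(45, k)
  ph <- matrix(runif(2 * k, 0, 2 * pi), k)
  X <- matrix(0, n_time, k)
  for (i in seq_len(k)) {
    X[, i] <- cos(2 * pi * fb[i] * t + ph[i, 1]) *
                (1 + SYNTH_MOD_DEPTH * M[, i]) +
              cos(2 * pi * fg[i] * t + ph[i, 2]) *
                (1 + SYNTH_MOD_DEPTH * M[, k + i])
  }
  if (spec$noise_sd > 0) {
    X <- X + spec$noise_sd * matrix(rnorm(n_time * k), n_time, k)
  }
  if (spec$artifacts) X <- inject_artifacts(X, fs)
  recording(X, fs, sprintf("EEG%d", seq_len(k)), "eeg", "uV")
}

# ocular-like slow transients plus brief high-amplitude spikes, for wICA tests
inject_artifacts <- function(X, fs, n_blinks = 5, n_spikes = 5) {
  n <- nrow(X); k <- ncol(X)
  for (b in seq_len(n_blinks)) {
    c0 <- sample.int(n, 1)
    width <- round(0.4 * fs)
    idx <- max(1, c0 - width):min(n, c0 + width)
    shape <- exp(-((idx - c0) / (0.15 * fs))^2)
    gain <- 10 * exp(-(seq_len(k) - 1) / 2)   # frontal-dominant
    X[idx, ] <- X[idx, ] + outer(shape, gain)
  }
  for (s in seq_len(n_spikes)) {
    c0 <- sample.int(n, 1)
    ch <- sample.int(k, 1)
    width <- round(0.01 * fs)
    idx <- max(1, c0 - width):min(n, c0 + width)
    X[idx, ch] <- X[idx, ch] + 30 * (1 - abs(idx - c0) / (width + 1))
  }
  X
}

#' Synthesize one subject's fNIRS data
#'
#' Slow (0.01-0.2 Hz) oxy- and deoxyhemoglobin fluctuations whose pairwise
#' channel correlations reproduce the subject's latent hbo and hbr
#' connectivity matrices, with a configurable negative mutual HbO-HbR
#' correlation, band-limited channel noise, and (per
#' `spec$fnirs_output`) either direct hemoglobin output or a forward
#' modified-Beer-Lambert projection to 760/850 nm optical densities with a
#' small linear drift, so the inversion can be tested round-trip.
#'
#' Consumes the current RNG stream; [generate_cohort()] seeds it.
#'
#' @param latent named list with `hbo` and `hbr` target correlation matrices.
#' @param spec a [cohort_spec()].
#' @return an [hb_series()] (`fnirs_output = "hb"`) or a list with `od_760`
#'   and `od_850` [recording()]s.
#' @export
synthesize_fnirs <- function(latent, spec) {
  fs <- spec$fnirs_fs
  k <- spec$fnirs_channels
  n_time <- round(spec$duration_s * fs)
  mix <- coupled_block_mixing(latent$hbo, latent$hbr, spec$hbo_hbr_corr)
  L <- correlated_band_latents(n_time, mix, 0.01, 0.2, fs)
  hbo <- SYNTH_HBO_AMP * L[, seq_len(k), drop = FALSE]
  hbr <- SYNTH_HBR_AMP * L[, k + seq_len(k), drop = FALSE]
  if (spec$noise_sd > 0) {
    h <- fir_bandpass(0.01, 0.2, fs,
                      order = min(500, 2 * floor((n_time - 1) / 2)))
    mknoise <- function(amp) {
      N <- fir_filter_zerophase(matrix(rnorm(n_time * k), n_time, k), h)
      N <- sweep(N, 2, apply(N, 2, sd), `/`)
      amp * spec$noise_sd * N
    }
    hbo <- hbo + mknoise(SYNTH_HBO_AMP)
    hbr <- hbr + mknoise(SYNTH_HBR_AMP)
  }
  labels <- sprintf("NIRS%02d", seq_len(k))
  hb <- hb_series(hbo, hbr, fs, labels)
  if (spec$fnirs_output == "hb") return(hb)
  od <- od_from_hb(hb)
  # slow per-channel drift on the optical densities; removed by the
  # band-pass/detrend stages downstream
  drift <- outer(seq_len(n_time) / n_time, runif(k, -0.005, 0.005))
  od$od_760$data <- od$od_760$data + drift
  od$od_850$data <- od$od_850$data + drift / 2
  od
}

#' Connectivity tables straight from the ground truth
#'
#' Builds a [cohort_table()] whose connectivity matrices are the generator's
#' latent matrices themselves, bypassing signal rendering and measurement.
#' Used for statistical replicate studies of the CPM and coupling stages
#' where signal-level noise is not the question.
#'
#' @param cohort a `synthetic_cohort` (signals not required).
#' @return a [cohort_table()].
#' @export
cohort_from_truth <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  truth <- cohort$truth
  mats <- lapply(seq_along(truth$latent), function(s) {
    mods <- names(truth$latent[[s]])
    out <- lapply(mods, function(m) {
      connectivity_matrix(truth$latent[[s]][[m]], modality = m,
                          subject_id = cohort$subjects[[s]]$id)
    })
    stats::setNames(out, mods)
  })
  names(mats) <- names(cohort$subjects)
  cohort_table(mats, truth$performance)
}
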