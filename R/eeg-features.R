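# EEG feature extraction: broadband filtering, wICA artifact correction, and
# spectro-temporal amplitude-modulation (AM) series.

#' Canonical EEG frequency band table
#'
#' The five classical bands used both as carrier bands and (with the `m-`
#' prefix) as modulation bands: delta 0.1-4, theta 4-8, alpha 8-12,
#' beta 12-30 and gamma 30-50 Hz.
#'
#' @return data.frame with columns `name`, `f_low`, `f_high` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_low = c(0.1, 4, 8, 12, 30),
    f_high = c(4, 8, 12, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' Valid carrier/modulator band pairs
#'
#' The envelope of a band-limited signal can only carry modulation frequencies
#' compatible with its carrier band (Bedrosian's constraint), which restricts
#' the meaningful carrier-m-modulator combinations to a fixed set of 14 pairs.
#' The enumeration is hard-coded rather than derived from a rule: the
#' admissible set is part of the method definition (note that alpha-m-alpha is
#' excluded while beta-m-beta and gamma-m-gamma are included).
#'
#' @return data.frame with columns `carrier`, `modulator` and `name`
#'   (e.g. `"beta_m_alpha"`), in a stable order.
#' @export
#' @examples
#' valid_modulation_pairs()
valid_modulation_pairs <- function() {
  pairs <- rbind(
    c("delta", "delta"),
    c("theta", "delta"), c("theta", "theta"),
    c("alpha", "delta"), c("alpha", "theta"),
    c("beta", "delta"), c("beta", "theta"), c("beta", "alpha"),
    c("beta", "beta"),
    c("gamma", "delta"), c("gamma", "theta"), c("gamma", "alpha"),
    c("gamma", "beta"), c("gamma", "gamma")
  )
  data.frame(
    carrier = pairs[, 1],
    modulator = pairs[, 2],
    name = paste(pairs[, 1], "m", pairs[, 2], sep = "_"),
    stringsAsFactors = FALSE
  )
}

#' Broadband band-pass filter for raw EEG
#'
#' Second-order Butterworth band-pass between 0.1 and 100 Hz, applied
#' forward-backward (zero phase) per channel.
#'
#' @param rec a [recording()] with `fs > 200` Hz.
#' @param f_low,f_high band edges in Hz.
#' @return a filtered `recording` of identical shape.
#' @export
bandpass_broadband <- function(rec, f_low = 0.1, f_high = 100) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * f_high) {
    stop(sprintf("sampling rate %.1f Hz is too low for the %.0f Hz band edge",
                 rec$fs, f_high), call. = FALSE)
  }
  bf <- signal::butter(2, c(f_low, f_high) / (rec$fs / 2), type = "pass")
  out <- apply(rec$data, 2, function(x) signal::filtfilt(bf, x))
  recording(out, rec$fs, rec$channel_labels, rec$modality, rec$units)
}

#' wICA parameters
#'
#' The two printed knobs of the wavelet-enhanced ICA cleaning step plus the
#' wavelet internals. `cleaning_tolerance` scales the per-level universal
#' threshold at which wavelet coefficients of an artifactual independent
#' component are amplitude-limited; `ic_artifact_threshold` scales the same
#' threshold to decide whether a component is artifactual at all.
#'
#' @param cleaning_tolerance positive scalar, default 1.4.
#' @param ic_artifact_threshold positive scalar, default 1.6.
#' @param wavelet wavelet family label; only `"d4"` (orthogonal Daubechies,
#'   4 taps) is currently implemented.
#' @param level decomposition depth; `NULL` uses `floor(log2(fs / 4))`.
#' @param seed integer seed for the deterministic ICA initialisation.
#' @return an object of class `wica_params`.
#' @export
wica_params <- function(cleaning_tolerance = 1.4, ic_artifact_threshold = 1.6,
                        wavelet = "d4", level = NULL, seed = 1L) {
  if (!is.numeric(cleaning_tolerance) || cleaning_tolerance <= 0) {
    stop("`cleaning_tolerance` must be > 0", call. = FALSE)
  }
  if (!is.numeric(ic_artifact_threshold) || ic_artifact_threshold <= 0) {
    stop("`ic_artifact_threshold` must be > 0", call. = FALSE)
  }
  wavelet <- match.arg(wavelet, "d4")
  structure(list(cleaning_tolerance = cleaning_tolerance,
                 ic_artifact_threshold = ic_artifact_threshold,
                 wavelet = wavelet, level = level, seed = as.integer(seed)),
            class = "wica_params")
}

#' Wavelet-enhanced ICA artifact correction
#'
#' Decomposes the channels into independent components (FastICA), applies a
#' periodized discrete wavelet transform to each component, amplitude-limits
#' coefficients that exceed an artifact criterion, inverts the transform and
#' reconstructs all channels from all corrected components. No component is
#' discarded, so neural content leaked into artifactual components survives.
#'
#' The artifact criterion is a per-decomposition-level universal threshold
#' `sigma_l * sqrt(2 log N)` with `sigma_l` a robust (MAD-based) scale
#' estimate of that level's coefficients. A component is flagged artifactual
#' when any coefficient exceeds `ic_artifact_threshold` times this threshold;
#' flagged components have their coefficients clipped at
#' `cleaning_tolerance` times it (soft amplitude limiting: the sub-threshold
#' part of every coefficient is kept).
#'
#' @param rec a [recording()] with at least 2 channels and more samples than
#'   channels.
#' @param params a [wica_params()] object.
#' @return a cleaned `recording` with the shape of the input.
#' @export
wica_clean <- function(rec, params = wica_params()) {
  stopifnot(inherits(rec, "recording"), inherits(params, "wica_params"))
  X <- rec$data
  C <- ncol(X); n <- nrow(X)
  if (C < 2) stop("wICA needs at least 2 channels", call. = FALSE)
  if (n <= C) stop("wICA needs more samples than channels", call. = FALSE)

  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / n
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-10) {
    stop("input is rank-deficient (constant or duplicated channels); ",
         "ICA decomposition is not possible", call. = FALSE)
  }

  dec <- with_local_seed(params$seed,
                         ica::icafast(Xc, nc = C, center = FALSE,
                                      maxit = 200, tol = 1e-6))
  S <- dec$S                      # n x C independent components
  M <- dec$M                      # mixing: Xc ~ S %*% t(M)
  # make the round trip exact even if ICA stopped before full convergence
  M <- t(qr.coef(qr(S), Xc))

  level <- params$level
  if (is.null(level)) level <- max(1L, floor(log2(rec$fs / 4)))

  tol <- params$cleaning_tolerance
  thr <- params$ic_artifact_threshold
  S_clean <- S
  if (is.finite(tol) && is.finite(thr)) {
    for (k in seq_len(C)) {
      padded <- pad_pow2(S[, k], level)
      cf <- dwt_forward(padded$x, level)
      uni <- sqrt(2 * log(length(padded$x)))
      bands <- c(cf$details, list(cf$approx))
      lim <- vapply(bands, function(w) {
        s <- mad(w, center = 0)
        if (s == 0) Inf else s * uni
      }, numeric(1))
      flagged <- any(mapply(function(w, l) any(abs(w) > thr * l),
                            bands, lim))
      if (flagged) {
        clip <- function(w, l) sign(w) * pmin(abs(w), tol * l)
        cf$details <- mapply(clip, cf$details, lim[seq_along(cf$details)],
                             SIMPLIFY = FALSE)
        cf$approx <- clip(cf$approx, lim[length(lim)])
        S_clean[, k] <- dwt_inverse(cf)[seq_len(padded$n)]
      }
    }
  }
  out <- S_clean %*% t(M)
  out <- sweep(out, 2, mu, `+`)
  recording(out, rec$fs, rec$channel_labels, rec$modality, rec$units)
}

#' Spectro-temporal amplitude-modulation series
#'
#' Per channel: linear-phase FIR band-pass to the carrier band, Hilbert
#' envelope (magnitude of the analytic signal), then a second FIR band-pass
#' of the envelope to the modulation band. All filters are applied with
#' integer group-delay compensation, so the output is zero-phase and channels
#' stay aligned. The first and last second are flagged for exclusion from
#' downstream correlations (filter and Hilbert edge transients).
#'
#' @param rec a filtered, cleaned [recording()].
#' @param pair a pair name such as `"beta_m_alpha"` or one row of
#'   [valid_modulation_pairs()].
#' @param transition_hz FIR transition bandwidth (Hz) used to set the order.
#' @return an `am_series` object (a `recording` subclass carrying the pair
#'   and a `trim_s` edge-exclusion attribute).
#' @export
#' @examples
#' fs <- 500; t <- seq(0, 20, by = 1 / fs)
#' x <- cos(2 * pi * 20 * t) * (1 + 0.5 * cos(2 * pi * 10 * t))
#' rec <- recording(cbind(x, x), fs)
#' am <- amplitude_modulation(rec, "beta_m_alpha")
amplitude_modulation <- function(rec, pair, transition_hz = 2) {
  stopifnot(inherits(rec, "recording"))
  vp <- valid_modulation_pairs()
  if (is.character(pair) && length(pair) == 1L) {
    if (!pair %in% vp$name) {
      stop(sprintf("'%s' is not a valid carrier-m-modulator pair; valid: %s",
                   pair, paste(vp$name, collapse = ", ")), call. = FALSE)
    }
    pair <- vp[vp$name == pair, ]
  } else if (is.data.frame(pair) && all(c("carrier", "modulator") %in% names(pair))) {
    key <- paste(pair$carrier[1], "m", pair$modulator[1], sep = "_")
    if (!key %in% vp$name) {
      stop(sprintf("'%s' is not a valid carrier-m-modulator pair; valid: %s",
                   key, paste(vp$name, collapse = ", ")), call. = FALSE)
    }
    pair <- vp[vp$name == key, ]
  } else {
    stop("`pair` must be a pair name or a carrier/modulator row", call. = FALSE)
  }
  bands <- eeg_bands()
  cb <- bands[bands$name == pair$carrier, ]
  mb <- bands[bands$name == pair$modulator, ]

  h_c <- fir_bandpass(cb$f_low, cb$f_high, rec$fs, transition_hz = transition_hz)
  h_m <- fir_bandpass(mb$f_low, mb$f_high, rec$fs, transition_hz = transition_hz)

  carrier <- fir_filter_zerophase(rec$data, h_c)
  env <- hilbert_envelope(carrier)
  am <- fir_filter_zerophase(env, h_m)

  out <- recording(am, rec$fs, rec$channel_labels,
                   modality = pair$name, units = rec$units)
  out$pair <- pair
  out$trim_s <- 1
  class(out) <- c("am_series", class(out))
  out
}

#' @export
print.am_series <- function(x, ...) {
  cat(sprintf("<am_series> %s (%s carrier, m-%s modulator)\n",
              x$modality, x$pair$carrier, x$pair$modulator))
  NextMethod()
}
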