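# fNIRS feature extraction: slow-wave band-pass, whole-record detrending, and
# the modified Beer-Lambert law (MBLL).

#' Default hemoglobin extinction coefficients
#'
#' Molar extinction coefficients of oxy- and deoxyhemoglobin at 760 and
#' 850 nm, in 1/(mM*cm), from the standard compiled hemoglobin absorption
#' spectrum widely used by fNIRS processing software. Shipped as explicit
#' configuration so concentration results are reproducible bit-for-bit.
#'
#' @return 2x2 matrix, rows `nm760`/`nm850`, columns `hbo`/`hbr`.
#' @export
default_extinction_coefficients <- function() {
  matrix(c(1.4866, 3.8437,
           2.5264, 1.7986),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("nm760", "nm850"), c("hbo", "hbr")))
}

#' Modified Beer-Lambert law parameters
#'
#' @param dpf_760,dpf_850 differential pathlength factors (dimensionless) for
#'   the 760 and 850 nm wavelengths; defaults 7.25 and 6.38. The pairing of
#'   the two printed DPF values with wavelengths follows the acquisition
#'   software's convention (larger DPF at the shorter wavelength); both are
#'   configurable.
#' @param source_detector_distance optode separation in mm (default 30).
#' @param extinction 2x2 extinction-coefficient matrix in 1/(mM*cm), rows =
#'   wavelengths (760, 850), columns = chromophores (HbO, HbR). Must be
#'   invertible.
#' @return an object of class `mbll_params`.
#' @export
mbll_params <- function(dpf_760 = 7.25, dpf_850 = 6.38,
                        source_detector_distance = 30,
                        extinction = default_extinction_coefficients()) {
  if (dpf_760 <= 0 || dpf_850 <= 0) stop("DPFs must be > 0", call. = FALSE)
  if (source_detector_distance <= 0) stop("distance must be > 0", call. = FALSE)
  extinction <- as.matrix(extinction)
  stopifnot(all(dim(extinction) == c(2, 2)))
  if (abs(det(extinction)) < 1e-12) {
    stop("extinction-coefficient matrix is singular", call. = FALSE)
  }
  structure(list(dpf_760 = dpf_760, dpf_850 = dpf_850,
                 source_detector_distance = source_detector_distance,
                 extinction = extinction),
            class = "mbll_params")
}

#' Slow-hemodynamics band-pass for fNIRS
#'
#' Linear-phase FIR band-pass between 0.01 and 0.2 Hz with group-delay
#' compensation, applied per channel. Records shorter than three periods of
#' the 0.01 Hz low edge produce a warning (the low edge is then poorly
#' resolved) but are filtered anyway.
#'
#' @param rec a [recording()] with `fs > 0.4` Hz.
#' @param f_low,f_high band edges in Hz.
#' @param order FIR order (even); default 500.
#' @return a filtered `recording`.
#' @export
fnirs_bandpass <- function(rec, f_low = 0.01, f_high = 0.2, order = 500) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * f_high) {
    stop(sprintf("sampling rate %.3f Hz too low for the %.2f Hz band edge",
                 rec$fs, f_high), call. = FALSE)
  }
  dur <- (n_samples(rec) + 0.5) / rec$fs
  if (dur < 3 / f_low) {
    warning(sprintf(
      "record of %.0f s is shorter than 3 periods of the %.2g Hz low edge",
      dur, f_low), call. = FALSE)
  }
  h <- fir_bandpass(f_low, f_high, rec$fs, order = order)
  out <- fir_filter_zerophase(rec$data, h)
  recording(out, rec$fs, rec$channel_labels, rec$modality, rec$units)
}

#' Remove the whole-record linear trend
#'
#' Least-squares linear detrending over the full record length, per channel,
#' applied before any segmentation.
#'
#' @param rec a [recording()].
#' @return a detrended `recording`.
#' @export
detrend_series <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  n <- n_samples(rec)
  t <- seq_len(n) - (n + 1) / 2            # centred time axis
  denom <- sum(t^2)
  X <- rec$data
  mu <- colMeans(X)
  slope <- colSums(t * sweep(X, 2, mu)) / denom
  out <- X - outer(rep(1, n), mu) - outer(t, slope)
  recording(out, rec$fs, rec$channel_labels, rec$modality, rec$units)
}

mbll_system_matrix <- function(params) {
  d_cm <- params$source_detector_distance / 10
  params$extinction * (d_cm * c(params$dpf_760, params$dpf_850))
}

#' Modified Beer-Lambert law inversion
#'
#' Solves, per channel and time point, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for the chromophore concentration changes, returned in micromolar.
#'
#' @param od_760,od_850 optical-density-change [recording()]s of equal shape
#'   and sampling rate.
#' @param params an [mbll_params()] object.
#' @return an [hb_series()].
#' @export
mbll <- function(od_760, od_850, params = mbll_params()) {
  stopifnot(inherits(od_760, "recording"), inherits(od_850, "recording"),
            inherits(params, "mbll_params"))
  if (!identical(dim(od_760$data), dim(od_850$data)) ||
      od_760$fs != od_850$fs) {
    stop("the two wavelength recordings must share shape and sampling rate",
         call. = FALSE)
  }
  A <- mbll_system_matrix(params)
  Ainv <- solve(A)
  # concentrations in mM -> uM
  hbo <- (Ainv[1, 1] * od_760$data + Ainv[1, 2] * od_850$data) * 1000
  hbr <- (Ainv[2, 1] * od_760$data + Ainv[2, 2] * od_850$data) * 1000
  hb_series(hbo, hbr, od_760$fs, od_760$channel_labels)
}

#' Forward-project hemoglobin concentrations to optical densities
#'
#' The forward counterpart of [mbll()]; used by the synthetic generator and
#' for round-trip verification.
#'
#' @param hb an [hb_series()] (uM).
#' @param params an [mbll_params()] object.
#' @return list with `od_760` and `od_850` [recording()]s.
#' @export
od_from_hb <- function(hb, params = mbll_params()) {
  stopifnot(inherits(hb, "hb_series"))
  A <- mbll_system_matrix(params)
  hbo_mM <- hb$hbo / 1000
  hbr_mM <- hb$hbr / 1000
  od760 <- A[1, 1] * hbo_mM + A[1, 2] * hbr_mM
  od850 <- A[2, 1] * hbo_mM + A[2, 2] * hbr_mM
  list(
    od_760 = recording(od760, hb$fs, hb$channel_labels, "od_760", "OD"),
    od_850 = recording(od850, hb$fs, hb$channel_labels, "od_850", "OD")
  )
}

#' Full fNIRS preprocessing chain
#'
#' Fixed order: band-pass (0.01-0.2 Hz) -> whole-record detrend -> MBLL.
#' Accepts either optical densities (two wavelengths) or raw intensities
#' (converted to dOD via `-log(I / mean(I))` per channel first).
#'
#' @param od_760,od_850 per-wavelength [recording()]s (OD changes, or raw
#'   intensities with `intensity = TRUE`).
#' @param params an [mbll_params()] object.
#' @param intensity logical; `TRUE` if inputs are raw light intensities.
#' @return an [hb_series()].
#' @export
process_fnirs <- function(od_760, od_850, params = mbll_params(),
                          intensity = FALSE) {
  if (intensity) {
    to_od <- function(r) {
      od <- -log(sweep(r$data, 2, colMeans(r$data), `/`))
      recording(od, r$fs, r$channel_labels, r$modality, "OD")
    }
    od_760 <- to_od(od_760); od_850 <- to_od(od_850)
  }
  od_760 <- detrend_series(fnirs_bandpass(od_760))
  od_850 <- detrend_series(fnirs_bandpass(od_850))
  mbll(od_760, od_850, params)
}
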