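# Internal signal-processing primitives shared by the EEG and fNIRS modules.

#' Design a linear-phase FIR band-pass filter
#'
#' Hamming-windowed design (via [signal::fir1]). The order defaults to the
#' value needed for roughly a 2 Hz transition band at the given sampling rate
#' (>= 40 dB stopband for the Hamming window), rounded up to an even number so
#' the group delay is an integer number of samples.
#'
#' @param f_low,f_high band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order; `NULL` chooses it from the transition-band rule.
#' @param transition_hz transition bandwidth used when `order` is `NULL`.
#' @return numeric vector of filter coefficients (odd length, symmetric).
#' @keywords internal
#' @noRd
fir_bandpass <- function(f_low, f_high, fs, order = NULL, transition_hz = 2) {
  stopifnot(f_low >= 0, f_high > f_low, f_high < fs / 2)
  if (is.null(order)) {
    order <- ceiling(3.3 * fs / transition_hz)
    order <- order + order %% 2
  }
  w <- c(f_low, f_high) / (fs / 2)
  as.numeric(signal::fir1(order, w, type = "pass"))
}

# Zero-phase application of a symmetric (linear-phase, odd-length) FIR filter:
# single FFT-based convolution with the integer group delay compensated, so
# there is no phase shift between channels and no squaring of the magnitude
# response. `x` may be a vector or a time x channel matrix.
fir_filter_zerophase <- function(x, h) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  L <- length(h)
  stopifnot(L %% 2 == 1)
  gd <- (L - 1) / 2
  nfft <- stats::nextn(n + L - 1, 2)
  H <- fft(c(h, rep(0, nfft - L)))
  X <- mvfft(rbind(x, matrix(0, nfft - n, ncol(x))))
  y <- Re(mvfft(X * H, inverse = TRUE)) / nfft
  y <- y[(gd + 1):(gd + n), , drop = FALSE]
  if (vec) drop(y) else y
}

# Analytic-signal magnitude (Hilbert envelope) per column, computed in the
# frequency domain.
hilbert_envelope <- function(x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  u <- rep(0, n)
  if (n %% 2 == 0) {
    u[1] <- 1; u[n / 2 + 1] <- 1; u[2:(n / 2)] <- 2
  } else {
    u[1] <- 1; u[2:((n + 1) / 2)] <- 2
  }
  X <- mvfft(x) * u
  env <- Mod(mvfft(X, inverse = TRUE) / n)
  if (vec) drop(env) else env
}

# Evaluate randomness-consuming code under a given seed without disturbing the
# caller's RNG stream.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Symmetric positive-semidefinite square root.
sqrtm_psd <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

# Project a symmetric matrix onto the correlation matrices (eigenvalue floor,
# then rescale to unit diagonal). Used so planted latent structure is always
# realisable as a correlation matrix.
nearest_correlation <- function(M, eig_floor = 1e-8) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) < eig_floor) {
    v <- pmax(e$values, eig_floor)
    M <- e$vectors %*% (v * t(e$vectors))
  }
  d <- 1 / sqrt(diag(M))
  M <- M * outer(d, d)
  diag(M) <- 1
  (M + t(M)) / 2
}

# ---- periodized orthogonal Daubechies (4-tap) discrete wavelet transform ----
# No wavelet package ships with this environment, so the pyramid algorithm is
# implemented directly. The filters are the exact Daubechies extremal-phase
# 4-tap pair; orthonormality gives perfect reconstruction, which the test
# suite checks.

daub4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- c(h[4], -h[3], h[2], -h[1])
  list(h = h, g = g)
}

dwt_step <- function(x, h, g) {
  n <- length(x)
  k <- seq_len(n / 2)
  a <- numeric(n / 2)
  d <- numeric(n / 2)
  for (m in 0:3) {
    idx <- (2 * (k - 1) + m) %% n + 1
    a <- a + h[m + 1] * x[idx]
    d <- d + g[m + 1] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a)
  x <- numeric(n)
  k <- seq_along(a)
  for (m in 0:3) {
    idx <- (2 * (k - 1) + m) %% n + 1
    contrib <- h[m + 1] * a + g[m + 1] * d
    # accumulate via tabulation: idx values are unique per m for periodized
    # even-length signals, so direct assignment-with-add is safe
    x[idx] <- x[idx] + contrib
  }
  x
}

# Full decomposition to `level` scales; input length must be a multiple of
# 2^level (callers pad). Returns list(details = list d1..dL, approx = aL).
dwt_forward <- function(x, level) {
  f <- daub4_filters()
  stopifnot(length(x) %% 2^level == 0)
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    s <- dwt_step(a, f$h, f$g)
    details[[l]] <- s$d
    a <- s$a
  }
  list(details = details, approx = a)
}

dwt_inverse <- function(coeffs) {
  f <- daub4_filters()
  a <- coeffs$approx
  for (l in rev(seq_along(coeffs$details))) {
    a <- idwt_step(a, coeffs$details[[l]], f$h, f$g)
  }
  a
}

# Reflection-pad a vector to a multiple of 2^level.
pad_pow2 <- function(x, level) {
  n <- length(x)
  block <- 2^level
  target <- ceiling(n / block) * block
  if (target == n) return(list(x = x, n = n))
  extra <- target - n
  pad <- rev(x)[seq_len(min(extra, n))]
  while (length(pad) < extra) pad <- c(pad, rev(pad))[seq_len(extra)]
  list(x = c(x, pad[seq_len(extra)]), n = n)
}
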