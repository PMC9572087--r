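# Frequency-domain feature block: spectral peaks, band powers, leading
# FFT magnitudes, spectral entropy and total harmonic distortion.

# One-sided Hann-windowed magnitude spectrum. Returns bin frequencies
# (Hz) and magnitudes; bin 1 is DC. Power normalization is chosen so
# that the per-bin powers of `power = TRUE` sum to (approximately) the
# signal variance for a zero-mean signal (Parseval).
magnitude_spectrum <- function(signal, fs) {
  n <- length(signal)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))  # Hann
  signal <- signal - mean(signal)  # avoid DC leakage through the window
  X <- fft(signal * w)
  nf <- floor(n / 2)
  idx <- 1:(nf + 1)  # DC .. Nyquist-ish
  mag <- Mod(X)[idx]
  # amplitude calibration: a unit sine aligned to a bin reads ~1
  mag <- mag * 2 / sum(w)
  list(freq = (idx - 1) * fs / n, mag = mag, n = n, win_ss = sum(w^2))
}

# Per-bin one-sided power with Parseval-consistent scaling.
power_spectrum <- function(signal, fs) {
  n <- length(signal)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- fft(signal * w)
  nf <- floor(n / 2)
  idx <- 1:(nf + 1)
  p <- Mod(X[idx])^2 / (n * sum(w^2) / n)  # = |X|^2 / sum(w^2)
  p <- p / n
  dbl <- rep(2, length(idx)); dbl[1] <- 1
  if (n %% 2 == 0) dbl[length(idx)] <- 1
  list(freq = (idx - 1) * fs / n, power = p * dbl)
}

# Indices (into a magnitude vector) of strict interior local maxima.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Height and position of the leading spectral peaks
#'
#' Local maxima of the Hann-windowed magnitude spectrum (DC excluded),
#' sorted by height descending. If fewer than `n_peaks` peaks exist the
#' remaining pairs are `(0, 0)`.
#'
#' @param signal numeric vector (a filtered channel).
#' @param fs sampling frequency in Hz.
#' @param n_peaks number of peaks to report (default 6).
#' @return Numeric vector of `2 * n_peaks` values, alternating height
#'   and position (Hz) per peak.
#' @export
spectral_peaks <- function(signal, fs, n_peaks = 6) {
  stopifnot(length(signal) >= 16)
  sp <- magnitude_spectrum(signal, fs)
  cand <- local_maxima(sp$mag)
  cand <- cand[cand > 1L]  # exclude DC
  heights <- sp$mag[cand]
  ord <- order(heights, decreasing = TRUE)
  cand <- cand[ord][seq_len(min(n_peaks, length(cand)))]
  h <- p <- rep(0, n_peaks)
  if (length(cand)) {
    h[seq_along(cand)] <- sp$mag[cand]
    p[seq_along(cand)] <- sp$freq[cand]
  }
  out <- as.numeric(rbind(h, p))
  names(out) <- as.vector(rbind(paste0("peak", 1:n_peaks, "_height"),
                                paste0("peak", 1:n_peaks, "_freq")))
  out
}

#' Total power in adjacent frequency bands
#'
#' Sums the one-sided periodogram power over each band `(lo, hi]`.
#' The default bands cover the locomotion fundamentals, their harmonics
#' and the residual high-frequency content: `(0.5, 3]`, `(3, 8]` and
#' `(8, min(17, fs/2)]` Hz (most activity information lies below 17 Hz).
#'
#' @param signal numeric vector.
#' @param fs sampling frequency in Hz.
#' @param bands list of `c(lo, hi)` pairs; edges must not exceed `fs/2`.
#' @return Numeric vector of band powers.
#' @export
band_power <- function(signal, fs, bands = default_bands(fs)) {
  for (b in bands)
    if (b[2] > fs / 2 + 1e-9) stop("band edge above the Nyquist frequency")
  ps <- power_spectrum(signal, fs)
  out <- vapply(bands, function(b)
    sum(ps$power[ps$freq > b[1] & ps$freq <= b[2]]), numeric(1))
  names(out) <- paste0("bandpower", seq_along(bands))
  out
}

#' @rdname band_power
#' @export
default_bands <- function(fs) {
  top <- min(17, fs / 2)
  list(c(0.5, 3), c(3, 8), c(8, top))
}

#' Leading FFT magnitudes and spectral entropy
#'
#' Magnitudes of the first three non-DC FFT bins (amplitude-scaled by
#' `2/n`) and the Shannon entropy (natural log) of the normalized
#' magnitude-squared spectrum over all non-DC bins. A zero signal yields
#' zero magnitudes and entropy 0.
#'
#' @param signal numeric vector of length `>= 8`.
#' @param fs sampling frequency in Hz.
#' @return Named numeric vector `c(fftmag1, fftmag2, fftmag3, fftentropy)`.
#' @export
fft_summary <- function(signal, fs) {
  n <- length(signal)
  stopifnot(n >= 8)
  X <- Mod(fft(signal))
  mags <- X[2:4] * 2 / n
  p2 <- X[2:(floor(n / 2) + 1)]^2
  tot <- sum(p2)
  ent <- 0
  if (tot > 0) {
    p <- p2[p2 > 0] / tot
    ent <- -sum(p * log(p))
  }
  c(fftmag1 = mags[1], fftmag2 = mags[2], fftmag3 = mags[3], fftentropy = ent)
}

#' Total harmonic distortion
#'
#' Ratio of the root-sum-square amplitude of harmonics 2..`n_harmonics+1`
#' to the amplitude at the fundamental,
#' `THD = sqrt(sum(Vn^2)) / Vfund`. The fundamental is the highest
#' non-DC peak of the magnitude spectrum; each harmonic amplitude is
#' read as the maximum magnitude within one bin of `n * f0` to tolerate
#' spectral leakage. A flat spectrum (no peak above the noise floor)
#' yields 0 with a warning.
#'
#' @param signal numeric vector.
#' @param fs sampling frequency in Hz.
#' @param n_harmonics number of harmonics beyond the fundamental
#'   (default 5, i.e. harmonics 2 through 6).
#' @return Scalar THD (dimensionless, `>= 0`).
#' @export
thd <- function(signal, fs, n_harmonics = 5) {
  sp <- magnitude_spectrum(signal, fs)
  mag <- sp$mag
  mag[1] <- 0
  i0 <- which.max(mag)
  if (mag[i0] <= 0 || mag[i0] < 4 * stats::median(mag[-1])) {
    warning("no spectral peak above the noise floor; THD defined as 0")
    return(0)
  }
  vfund <- mag[i0]
  k0 <- i0 - 1L  # fundamental bin index (DC = 0)
  nf <- length(mag) - 1L
  vh <- vapply(2:(n_harmonics + 1), function(h) {
    kb <- h * k0
    if (kb - 1L > nf) return(0)
    idx <- (kb - 1L):(min(kb + 1L, nf)) + 1L
    max(mag[idx])
  }, numeric(1))
  sqrt(sum(vh^2)) / vfund
}
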