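# Spectral estimation primitives: Welch power spectral density and a
# short-time band-power spectrogram. Written against the definitions used
# throughout the analysis (Hann taper, 50% overlap, one-sided density
# normalized so that white noise of variance s^2 sampled at fs has density
# 2*s^2/fs); validated in tests against a direct DFT oracle and Parseval.

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with a Hann taper and 50% overlap.
#' Segments are demeaned individually. One-sided density in units^2/Hz.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param window_sec segment length in seconds (default 1).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list with `freq` (Hz, excludes DC) and `psd`.
#' @export
welch_psd <- function(x, fs, window_sec = 1, overlap = 0.5) {
  nw <- round(window_sec * fs)
  if (length(x) < nw) stopf("welch_psd: epoch (%d samples) shorter than one %g s window", length(x), window_sec)
  hop <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  w <- hann_window(nw)
  scale <- 1 / (fs * sum(w^2))
  acc <- numeric(nw)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc * scale / length(starts)
  # one-sided: fold negative frequencies
  half <- floor(nw / 2)
  freq <- (1:half) * fs / nw
  psd <- 2 * p[2:(half + 1)]
  if (nw %% 2 == 0) psd[half] <- psd[half] / 2  # Nyquist bin is unpaired
  list(freq = freq, psd = psd)
}

# Interpolate a PSD onto target bin-center frequencies (linear in the
# stated axes). Used for the log-spaced 1-100 Hz grid (slope fits) and the
# linear 500 Hz grid (multiunit band power).
interp_psd <- function(freq, psd, centers, log_axes = FALSE) {
  if (log_axes) {
    out <- stats::approx(log10(freq), log10(pmax(psd, .Machine$double.xmin)),
                         xout = log10(centers), rule = 2)$y
    10^out
  } else {
    stats::approx(freq, psd, xout = centers, rule = 2)$y
  }
}

#' Short-time summed band power (spectrogram reduction)
#'
#' Per time step: Hann-tapered periodogram of one window, interpolated onto
#' linearly spaced bin centers (`bin_hz` apart) spanning `band`, then summed.
#' This is the multiunit-power reduction used for laminar maps.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz); must resolve the upper band edge.
#' @param window_sec window length in seconds.
#' @param band two-element band in Hz (default `c(500, 5000)`).
#' @param bin_hz bin spacing inside the band (default 500).
#' @param overlap fractional overlap (default 0.5).
#' @return list with `time` (window centers, s, relative to epoch start)
#'   and `power` (summed band power per step).
#' @export
stft_band_power <- function(x, fs, window_sec = 0.004, band = c(500, 5000),
                            bin_hz = 500, overlap = 0.5) {
  if (fs < 2 * band[2]) stopf("stft_band_power: sampling rate %g Hz cannot resolve %g Hz", fs, band[2])
  nw <- round(window_sec * fs)
  if (length(x) < nw) stopf("stft_band_power: epoch shorter than one window")
  hop <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  w <- hann_window(nw)
  scale <- 1 / (fs * sum(w^2))
  half <- floor(nw / 2)
  freq <- (1:half) * fs / nw
  centers <- seq(band[1], band[2], by = bin_hz)
  pow <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- 2 * scale * Mod(stats::fft(seg))[2:(half + 1)]^2
    if (nw %% 2 == 0) p[half] <- p[half] / 2
    pow[i] <- sum(interp_psd(freq, p, centers))
  }
  list(time = (starts - 1 + nw / 2) / fs, power = pow)
}

#' Synthesize Gaussian noise with a power-law spectrum
#'
#' Spectral synthesis: unit-variance white Gaussian coefficients shaped so
#' the power spectrum follows 1/f^alpha over all nonzero frequencies, then
#' rescaled to the requested standard deviation. `alpha = 0` gives white
#' noise; `alpha = 2` a random-walk-like spectrum.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param alpha spectral exponent (power ~ 1/f^alpha).
#' @param sd target standard deviation of the trace.
#' @return numeric vector of length `n`.
#' @export
colored_noise <- function(n, fs, alpha = 1, sd = 1) {
  nfft <- n
  half <- floor(nfft / 2)
  f <- (1:half) * fs / nfft
  amp <- f^(-alpha / 2)
  re <- stats::rnorm(half)
  im <- stats::rnorm(half)
  spec <- complex(real = re, imaginary = im) * amp
  full <- complex(length.out = nfft)
  full[2:(half + 1)] <- spec
  if (nfft %% 2 == 0) full[half + 1] <- complex(real = re[half] * amp[half], imaginary = 0)
  full[nfft:(nfft - half + 2)] <- Conj(spec[1:(half - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / nfft
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}
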