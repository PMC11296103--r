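# Minimal signal-processing primitives.  No DSP dependency is assumed: the
# band-pass is a zero-phase FFT brick wall, which is adequate for the
# band-power and envelope computations used here (no causal filtering needed).

# Deterministic 32-bit-safe seed derivation: keeps every derived seed in
# [0, 2^31 - 5e4) so small offsets added downstream never overflow.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k)) %% 2147400000)
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Tukey (tapered cosine) window: cosine ramps over fraction r/2 at each
# end, flat middle.  Used as the spindle amplitude envelope: waxing-waning
# edges with a sustained body, so nominal and visible duration coincide.
tukey_window <- function(n, r = 0.3) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  hi <- t > 1 - r / 2
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / r - 1)))
  w
}

# Zero-phase band-pass by FFT masking with raised-cosine transition bands
# (default 2 Hz) outside [lo, hi].  The taper keeps the impulse response
# compact in time; a brick-wall mask rings (sinc tails) far beyond the
# event, which would, e.g., leak spike energy into a gamma precursor
# window.  Returns a vector of the same length as x.
fft_bandpass <- function(x, sfreq, lo, hi, taper = 2) {
  n <- length(x)
  X <- fft(x)
  f <- seq(0, n - 1) / n * sfreq
  f <- pmin(f, sfreq - f)          # mirror frequencies
  w <- numeric(n)
  w[f >= lo & f <= hi] <- 1
  if (taper > 0) {
    lo_t <- f >= lo - taper & f < lo
    w[lo_t] <- 0.5 + 0.5 * cos(pi * (lo - f[lo_t]) / taper)
    hi_t <- f > hi & f <= hi + taper
    w[hi_t] <- 0.5 + 0.5 * cos(pi * (f[hi_t] - hi) / taper)
  }
  Re(fft(X * w, inverse = TRUE)) / n
}

# Centered moving average with shrinking windows at the edges (no NA).
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  len <- length(x)
  hl <- floor((n - 1) / 2)
  hr <- n - 1 - hl
  cs <- cumsum(c(0, x))
  i <- seq_len(len)
  lo <- pmax(i - hl, 1)
  hi <- pmin(i + hr, len)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms over Hann-windowed segments with 50%
#' overlap. Used for spectral-slope checks of the synthetic background and
#' available for general diagnostics.
#'
#' @param x numeric signal vector.
#' @param sfreq sampling rate in Hz.
#' @param nperseg segment length in samples (default 1024, truncated to the
#'   signal length).
#' @return list with `freq` (Hz) and `psd` (power per Hz, arbitrary units).
#' @export
welch_psd <- function(x, sfreq, nperseg = 1024) {
  nperseg <- min(nperseg, length(x))
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, length(x) - nperseg + 1, by = step)
  w <- hann_window(nperseg)
  norm <- sum(w^2) * sfreq
  acc <- numeric(nperseg)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)]
    seg <- (seg - mean(seg)) * w
    acc <- acc + Mod(fft(seg))^2 / norm
  }
  psd <- acc / length(starts)
  nf <- floor(nperseg / 2)
  list(freq = seq(0, nf) * sfreq / nperseg, psd = psd[seq_len(nf + 1)])
}

# Dominant frequency of a short segment by zero-padded periodogram peak,
# restricted to [fmin, fmax].
periodogram_peak <- function(x, sfreq, fmin, fmax, nfft = NULL) {
  n <- length(x)
  if (is.null(nfft)) nfft <- max(8192L, 2L^ceiling(log2(n)))
  seg <- (x - mean(x)) * hann_window(n)
  seg <- c(seg, numeric(nfft - n))
  P <- Mod(fft(seg))^2
  f <- seq(0, nfft - 1) / nfft * sfreq
  keep <- which(f >= fmin & f <= fmax)
  f[keep[which.max(P[keep])]]
}

# Excess kurtosis (0 for a normal sample in expectation).
excess_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

# 1/f^beta Gaussian noise via spectral shaping, unit variance.
pink_noise <- function(n, beta) {
  w <- rnorm(n)
  X <- fft(w)
  f <- seq(0, n - 1) / n
  f <- pmin(f, 1 - f)
  scale <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(fft(X * scale, inverse = TRUE)) / n
  x / sd(x)
}
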