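# Zero-phase frequency-domain filtering primitives shared by the synthetic
# generator and the preprocessing chain. A real, nonnegative gain applied to
# the DFT is exactly zero-phase and is stable for any band placement, including
# the 1-4 Hz band at a 6000 Hz sampling rate where transfer-function IIR
# band-passes lose numerical stability.

# Raised-cosine band-pass gain evaluated on the folded DFT frequency grid.
bandpass_gain <- function(n, fs, lo, hi, transition = NULL) {
  if (is.null(transition)) {
    transition <- max(min(0.1 * (hi - lo), 0.5 * lo), 0.05)
  }
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f) # fold negative-frequency bins
  g <- numeric(n)
  g[f >= lo & f <= hi] <- 1
  rise <- f > (lo - transition) & f < lo
  g[rise] <- 0.5 * (1 + cos(pi * (lo - f[rise]) / transition))
  fall <- f > hi & f < (hi + transition)
  g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - hi) / transition))
  g
}

# Fraction of white-noise power a gain vector retains; used to renormalize
# band-limited components to a target variance.
gain_power_fraction <- function(gain) mean(gain^2)

# Apply a DFT-domain gain to each column of a samples x channels matrix.
apply_fft_gain <- function(x, gain) {
  x <- as.matrix(x)
  stopifnot(length(gain) == nrow(x))
  xf <- stats::mvfft(x)
  Re(stats::mvfft(xf * gain, inverse = TRUE)) / nrow(x)
}

fft_bandpass <- function(x, fs, lo, hi, transition = NULL) {
  apply_fft_gain(as.matrix(x), bandpass_gain(nrow(as.matrix(x)), fs, lo, hi, transition))
}

# Biquad notch (constrained direct-form coefficients), applied forward and
# backward for zero phase. Q = 30 gives a -3 dB width of f0/30 (~1.7 Hz at
# 50 Hz), leaving the +-5 Hz neighbourhood essentially untouched.
notch_coefficients <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}
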