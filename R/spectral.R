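#' Welch power spectral density
#'
#' Mean modified periodogram over 50%-overlapping Hann-windowed segments,
#' one-sided, density scaling.
#'
#' @param x Numeric vector.
#' @param fs Sample rate, Hz.
#' @param nperseg Segment length (default 4 s of samples).
#' @param nfft FFT length (>= `nperseg`); zero-padding refines the frequency
#'   grid.
#' @return List with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, nperseg = round(4 * fs), nfft = NULL) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  if (is.null(nfft)) nfft <- nperseg
  stopifnot(nfft >= nperseg)
  step <- max(floor(nperseg / 2), 1)
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nperseg) / (nperseg + 1)))
  u <- sum(w ^ 2)
  nf <- floor(nfft / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s + seq_len(nperseg) - 1]
    seg <- (seg - mean(seg)) * w
    X <- fft(c(seg, numeric(nfft - nperseg)))
    acc <- acc + Mod(X[seq_len(nf)]) ^ 2
  }
  psd <- acc / length(starts) / (fs * u)
  psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  list(freq = (seq_len(nf) - 1) * fs / nfft, psd = psd)
}

#' Analytic signal via the FFT method
#'
#' @param x Real-valued vector.
#' @return Complex vector whose real part is `x` and imaginary part its
#'   Hilbert transform.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# band-limited analytic signal: positive-frequency band selection in the
# spectrum; robust on short epochs where an IIR band-pass would be dominated
# by edge transients
band_analytic <- function(x, fs, band) {
  n <- length(x)
  f <- (seq_len(n) - 1) * fs / n
  X <- fft(x)
  keep <- f >= band[1] & f <= band[2] & f <= fs / 2
  X[!keep] <- 0
  2 * fft(X, inverse = TRUE) / n
}
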