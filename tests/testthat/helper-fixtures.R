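# deterministic fixture participants built in code

fixture_participant <- function(pitch = 4000, intensity = 60,
                                group = "TRT", well_identified = TRUE,
                                hl_left = NULL, hl_right = NULL) {
  freqs <- c(125, 250, 500, 1000, 2000, 4000, 8000)
  if (is.null(hl_left)) hl_left <- c(10, 10, 12, 15, 20, 30, 40)
  if (is.null(hl_right)) hl_right <- hl_left
  structure(list(
    id = "PX", condition = "tinnitus", age = 45, sex = "F", heart_rate = 72,
    audiogram = new_audiogram(hl_left, hl_right, freqs),
    tinnitus = new_tinnitus_profile(pitch, intensity, "B", well_identified),
    group = group,
    thi_score = c(S0 = 40, Sf = 40),
    hads_anxiety = c(S0 = 8, Sf = 8),
    hads_stress = c(S0 = 8, Sf = 8)
  ), class = "participant")
}

fixture_healthy <- function() {
  p <- fixture_participant()
  p$condition <- "healthy"; p$tinnitus <- NULL; p$group <- "control"
  p
}

# dominant FFT peak frequency of a signal segment
fft_peak <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x)))[seq_len(floor(n / 2))]
  (which.max(sp) - 1) * fs / n
}

# fraction of Welch power inside a band
band_power_fraction <- function(x, fs, band) {
  ps <- welch_psd(x, fs, nperseg = min(length(x), round(fs / 2)))
  sum(ps$psd[ps$freq >= band[1] & ps$freq <= band[2]]) / sum(ps$psd)
}

# raw spectral band power (one channel)
band_power <- function(x, fs, band) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x))[seq_len(floor(n / 2))]) ^ 2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(p[f >= band[1] & f <= band[2]])
}
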