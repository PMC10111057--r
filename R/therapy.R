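#' @importFrom signal butter filtfilt
NULL

new_therapy_program <- function(wave, fs, therapy, meta) {
  structure(list(wave = wave, fs = fs, therapy = therapy, meta = meta),
            class = "therapy_program")
}

db_to_amp <- function(db) 10 ^ (db / 20)

rms <- function(x) sqrt(mean(x ^ 2))

# raised-cosine onset/offset ramps, ramp duration in seconds
apply_ramps <- function(x, fs, ramp_s = 0.01) {
  n <- length(x)
  nr <- min(round(ramp_s * fs), floor(n / 2))
  if (nr > 0) {
    r <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(r)
  }
  x
}

pure_tone <- function(freq, duration, fs, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, by = 1 / fs, length.out = round(duration * fs)))
}

# scale so that no sample exceeds full scale; report the gain applied
peak_normalize <- function(wave, limit = 1) {
  pk <- max(abs(wave), 0)
  gain <- if (pk > limit) limit / pk else 1
  list(wave = wave * gain, gain = gain)
}

#' Synthesize a tinnitus-retraining-therapy (TRT) noise band
#'
#' Broadband noise band-pass filtered to the one-octave band centered at the
#' participant's tinnitus pitch (edges at pitch / sqrt(2) and pitch * sqrt(2);
#' 4th-order Butterworth applied forward-backward), presented below the
#' perceived tinnitus level by a configurable offset.
#'
#' The digital reference level maps tinnitus intensity i (0--100 dB) to an
#' RMS of `10^((i - 100) / 20)` full scale, so intensity 100 sits at 0 dB FS;
#' the output RMS is that reference minus `level_offset_db`.
#'
#' @param p A `participant` with a tinnitus profile.
#' @param duration Seconds of audio (0 gives an empty waveform with metadata).
#' @param fs Sample rate, Hz; must exceed twice the upper band edge.
#' @param level_offset_db Presentation level below the tinnitus level, dB.
#' @param seed Optional integer seed.
#' @return A `therapy_program`; metadata records the band edges and levels.
#' @export
synthesize_trt <- function(p, duration = 10, fs = 44100,
                           level_offset_db = 5, seed = NULL) {
  if (is.null(p$tinnitus)) stop("participant has no tinnitus profile")
  pitch <- p$tinnitus$pitch
  edges <- pitch * 2 ^ c(-0.5, 0.5)
  if (edges[2] >= fs / 2) stop("octave band exceeds the Nyquist frequency")
  if (!is.null(seed)) set.seed(seed)
  meta <- list(center = pitch, band = edges,
               level_offset_db = level_offset_db)
  n <- round(duration * fs)
  if (n == 0)
    return(new_therapy_program(numeric(0), fs, "TRT", meta))
  bp <- butter(4, edges / (fs / 2), type = "pass")
  x <- filtfilt(bp, rnorm(n))
  target_rms <- db_to_amp(p$tinnitus$intensity - 100 - level_offset_db)
  x <- x / rms(x) * target_rms
  pn <- peak_normalize(x)
  meta$rms <- rms(pn$wave); meta$gain <- pn$gain
  new_therapy_program(pn$wave, fs, "TRT", meta)
}

#' Synthesize an auditory-discrimination-therapy (ADT) oddball train
#'
#' Random sequence of tone pulses: the standard pulse at the tinnitus pitch,
#' the deviant 10% higher. Pulses are 100 ms with 10-ms raised-cosine ramps,
#' separated by gaps drawn uniformly from 0.5--1.5 s. Per-pulse level
#' compensates the hearing loss interpolated from the audiogram at the pulse
#' frequency (gain in dB equal to the loss, relative to the smallest pulse
#' gain, then peak-normalized).
#'
#' @param p A `participant` with a tinnitus profile and audiogram.
#' @param n_pulses Number of pulses.
#' @param p_deviant Deviant probability in \[0, 1).
#' @param fs Sample rate, Hz.
#' @param pulse_s,ramp_s,gap_range Pulse length, ramp length, gap bounds (s).
#' @param seed Optional integer seed; fixes the pulse identities and gaps.
#' @return A `therapy_program`; `meta$schedule` lists onset, frequency and
#'   type (`standard`/`deviant`) of every pulse.
#' @export
synthesize_adt <- function(p, n_pulses = 50, p_deviant = 0.2, fs = 44100,
                           pulse_s = 0.1, ramp_s = 0.01,
                           gap_range = c(0.5, 1.5), seed = NULL) {
  if (is.null(p$tinnitus)) stop("participant has no tinnitus profile")
  stopifnot(p_deviant >= 0, p_deviant < 1, n_pulses >= 1)
  f_std <- p$tinnitus$pitch
  f_dev <- 1.10 * f_std
  if (f_dev >= fs / 2) stop("deviant frequency exceeds the Nyquist frequency")
  if (!is.null(seed)) set.seed(seed)
  is_dev <- runif(n_pulses) < p_deviant
  gaps <- runif(n_pulses, gap_range[1], gap_range[2])
  onsets <- cumsum(c(0, (pulse_s + gaps)[-n_pulses]))
  freqs <- ifelse(is_dev, f_dev, f_std)
  gain_db <- hearing_loss_at(p$audiogram, freqs)
  gain_db <- gain_db - min(gain_db)
  total <- onsets[n_pulses] + pulse_s + gaps[n_pulses]
  wave <- numeric(ceiling(total * fs))
  for (k in seq_len(n_pulses)) {
    tone <- apply_ramps(pure_tone(freqs[k], pulse_s, fs, db_to_amp(gain_db[k])),
                        fs, ramp_s)
    i0 <- round(onsets[k] * fs)
    wave[i0 + seq_along(tone)] <- wave[i0 + seq_along(tone)] + tone
  }
  pn <- peak_normalize(wave)
  meta <- list(f_standard = f_std, f_deviant = f_dev,
               schedule = data.frame(onset = onsets, freq = freqs,
                                     type = ifelse(is_dev, "deviant", "standard"),
                                     gain_db = gain_db),
               pulse_s = pulse_s, gain = pn$gain)
  new_therapy_program(pn$wave, fs, "ADT", meta)
}

#' Synthesize an enriched-acoustic-environment (TEAE) tone sequence
#'
#' Random sequence of short tone pips spanning the audiogram frequency range,
#' each pip's amplitude proportional to the interpolated hearing loss at its
#' frequency (linear in dB HL, floor amplitude at zero loss), with
#' frequencies inside a notch around the tinnitus pitch excluded.
#'
#' @param p A `participant` with an audiogram.
#' @param duration Target duration, seconds.
#' @param fs Sample rate, Hz.
#' @param notch_octaves Full notch width around the tinnitus pitch, octaves.
#' @param pip_s Pip length, seconds.
#' @param amp_per_db Linear amplitude per dB HL.
#' @param floor_amp Amplitude at zero hearing loss.
#' @param seed Optional integer seed.
#' @return A `therapy_program`; `meta$schedule` records every pip.
#' @export
synthesize_teae <- function(p, duration = 10, fs = 44100,
                            notch_octaves = 1 / 3, pip_s = 0.06,
                            amp_per_db = 0.01, floor_amp = 0.02, seed = NULL) {
  ag <- p$audiogram
  if (is.null(ag) || length(ag$freqs) == 0) stop("participant has no audiogram")
  if (!is.null(seed)) set.seed(seed)
  fr <- range(ag$freqs)
  notch <- if (!is.null(p$tinnitus))
    p$tinnitus$pitch * 2 ^ (c(-1, 1) * notch_octaves / 2) else c(NA, NA)
  n <- round(duration * fs)
  wave <- numeric(n)
  onsets <- freqs <- amps <- numeric(0)
  t0 <- 0
  while (t0 + pip_s < duration) {
    f <- 2 ^ runif(1, log2(fr[1]), log2(min(fr[2], fs / 2 * 0.9)))
    if (!is.na(notch[1]) && f >= notch[1] && f <= notch[2]) next
    hl <- hearing_loss_at(ag, f)
    a <- floor_amp + amp_per_db * max(hl, 0)
    if (hl <= 0) a <- floor_amp
    tone <- apply_ramps(pure_tone(f, pip_s, fs, a), fs, 0.01)
    i0 <- round(t0 * fs)
    idx <- i0 + seq_along(tone)
    idx <- idx[idx <= n]
    wave[idx] <- wave[idx] + tone[seq_along(idx)]
    onsets <- c(onsets, t0); freqs <- c(freqs, f); amps <- c(amps, a)
    t0 <- t0 + pip_s + runif(1, 0.05, 0.3)
  }
  pn <- peak_normalize(wave)
  meta <- list(notch = notch, amp_per_db = amp_per_db, floor_amp = floor_amp,
               schedule = data.frame(onset = onsets, freq = freqs, amp = amps),
               gain = pn$gain)
  new_therapy_program(pn$wave, fs, "TEAE", meta)
}

#' Synthesize a binaural-beats-therapy (BBT) dichotic tone pair
#'
#' Stereo output: the left channel carries a pure tone at the tinnitus pitch
#' (the carrier), the right channel a tone `beat_hz` higher, at constant
#' amplitude. Only patients with tinnitus pitch below 1 kHz are eligible.
#'
#' @param p A `participant` with tinnitus pitch < 1000 Hz.
#' @param beat_hz Beat (frequency difference), Hz; default 10 Hz targets the
#'   alpha band.
#' @param duration Seconds.
#' @param fs Sample rate, Hz.
#' @param amp Per-channel amplitude (constant).
#' @return A `therapy_program` whose `wave` is an n x 2 matrix
#'   (columns left, right).
#' @export
synthesize_bbt <- function(p, beat_hz = 10, duration = 10, fs = 44100,
                           amp = 0.5) {
  if (is.null(p$tinnitus)) stop("participant has no tinnitus profile")
  pitch <- p$tinnitus$pitch
  if (pitch >= 1000)
    stop("BBT eligibility requires tinnitus pitch below 1 kHz")
  stopifnot(beat_hz >= 0)
  left <- pure_tone(pitch, duration, fs, amp)
  right <- pure_tone(pitch + beat_hz, duration, fs, amp)
  wave <- cbind(left = apply_ramps(left, fs), right = apply_ramps(right, fs))
  new_therapy_program(wave, fs, "BBT",
                      list(carrier = pitch, beat_hz = beat_hz, amp = amp))
}

#' Synthesize untuned placebo music
#'
#' Procedurally generated tonal sequence at a relaxing tempo (60--80 beats
#' per minute): one pentatonic note per beat with an exponentially decaying
#' envelope, not tuned to any tinnitus parameter.
#'
#' @param duration Seconds.
#' @param fs Sample rate, Hz.
#' @param tempo_bpm Beats per minute, within \[60, 80\].
#' @param seed Optional integer seed.
#' @return A `therapy_program`; `meta$beat_period` is `60 / tempo_bpm` s.
#' @export
synthesize_placebo <- function(duration = 10, fs = 44100, tempo_bpm = 70,
                               seed = NULL) {
  if (tempo_bpm < 60 || tempo_bpm > 80)
    stop("tempo must lie within [60, 80] beats per minute")
  if (!is.null(seed)) set.seed(seed)
  period <- 60 / tempo_bpm
  scale_hz <- 220 * 2 ^ (c(0, 3, 5, 7, 10, 12) / 12)  # A minor pentatonic
  n <- round(duration * fs)
  wave <- numeric(n)
  onsets <- seq(0, duration - 1e-9, by = period)
  for (t0 in onsets) {
    f <- sample(scale_hz, 1)
    len <- min(round(period * fs), n - round(t0 * fs))
    if (len <= 0) next
    tt <- seq(0, by = 1 / fs, length.out = len)
    note <- sin(2 * pi * f * tt) * exp(-tt / (period / 3)) * 0.6
    idx <- round(t0 * fs) + seq_len(len)
    wave[idx] <- wave[idx] + note
  }
  pn <- peak_normalize(wave)
  new_therapy_program(pn$wave, fs, "placebo",
                      list(tempo_bpm = tempo_bpm, beat_period = period,
                           onsets = onsets, gain = pn$gain))
}

#' Build the EEG-session stimulation schedule
#'
#' Regular stimulus train: `n_stimuli` onsets at multiples of
#' `stim_duration + iti`. The default reproduces the monitoring protocol:
#' 50 one-second stimuli with a 2-s inter-trial interval (150 s total).
#'
#' @param n_stimuli Number of stimuli (> 0).
#' @param stim_duration Stimulus length, s (> 0).
#' @param iti Inter-trial interval, s (> 0).
#' @return A `stimulation_schedule`: list with `onsets` (s), `stim_duration`,
#'   `iti` and `total` duration (s).
#' @export
build_schedule <- function(n_stimuli = 50, stim_duration = 1, iti = 2) {
  stopifnot(n_stimuli > 0, stim_duration > 0, iti > 0)
  onsets <- (seq_len(n_stimuli) - 1) * (stim_duration + iti)
  structure(list(onsets = onsets, stim_duration = stim_duration, iti = iti,
                 total = n_stimuli * (stim_duration + iti)),
            class = "stimulation_schedule")
}
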