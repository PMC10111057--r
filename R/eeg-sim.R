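#' @importFrom stats fft mad sd
NULL

new_eeg_recording <- function(data, fs, channels, events = NULL,
                              session = "rest") {
  stopifnot(nrow(data) == length(channels))
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = character(0))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices out of bounds")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels,
                 events = events, session = session),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, x$session, nrow(x$events)))
  invisible(x)
}

#' Component specification table for evoked-response templates
#'
#' Literature-informed amplitudes and latencies of the N1, P2 and P3
#' deflections for tinnitus sufferers and healthy controls: N1 control
#' (-2.2 uV, 80 ms) vs tinnitus (-1.7 uV, 150 ms); P2 control (2.9 uV,
#' 207 ms) vs tinnitus (2.4 uV, 250 ms); P3 control (4 uV, 340 ms) vs
#' tinnitus (2.6 uV, 380 ms). Widths (Gaussian sd, ms) are conventional
#' choices for each component's time scale.
#'
#' @param condition `"tinnitus"` or `"control"`.
#' @return Data frame with columns `name`, `amplitude` (uV), `latency` (ms),
#'   `width` (ms).
#' @export
aerp_components <- function(condition = c("tinnitus", "control")) {
  condition <- match.arg(condition)
  if (condition == "tinnitus") {
    data.frame(name = c("N1", "P2", "P3"),
               amplitude = c(-1.7, 2.4, 2.6),
               latency = c(150, 250, 380),
               width = c(15, 25, 40), stringsAsFactors = FALSE)
  } else {
    data.frame(name = c("N1", "P2", "P3"),
               amplitude = c(-2.2, 2.9, 4.0),
               latency = c(80, 207, 340),
               width = c(15, 25, 40), stringsAsFactors = FALSE)
  }
}

epoch_time_axis <- function(window, fs) {
  n_pre <- round(-window[1] * fs / 1000)
  n_tot <- round((window[2] - window[1]) * fs / 1000)
  (seq_len(n_tot) - 1 - n_pre) / fs * 1000
}

#' Build a single-channel evoked-component template
#'
#' Sum of Gaussian-windowed deflections, one per component row, with signed
#' amplitudes in microvolts over an epoch window relative to stimulus onset.
#'
#' @param components Data frame as returned by [aerp_components()].
#' @param window Epoch window in ms, e.g. `c(-200, 800)`.
#' @param fs Sample rate, Hz.
#' @return List of class `aerp_template`: `wave` (uV), `times` (ms), `fs`,
#'   `components`.
#' @export
make_template <- function(components, window = c(-200, 800), fs = 256) {
  times <- epoch_time_axis(window, fs)
  if (nrow(components) &&
      (any(components$latency < window[1]) || any(components$latency > window[2])))
    stop("component latency outside the epoch window")
  if (nrow(components) && any(components$width <= 0))
    stop("component width must be positive")
  wave <- numeric(length(times))
  for (i in seq_len(nrow(components))) {
    wave <- wave + components$amplitude[i] *
      exp(-0.5 * ((times - components$latency[i]) / components$width[i]) ^ 2)
  }
  structure(list(wave = wave, times = times, fs = fs, components = components),
            class = "aerp_template")
}

#' 1/f background noise
#'
#' Gaussian noise shaped to a 1/f power spectrum (amplitude 1/sqrt(f)) with
#' a white floor, normalized to unit standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sample rate, Hz.
#' @param white_frac Fraction of variance contributed by the white floor.
#' @return Numeric vector, sd 1.
#' @export
pink_noise <- function(n, fs = 256, white_frac = 0.2) {
  w <- rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]            # mirror to physical frequency
  scale <- 1 / sqrt(pmax(f, f[2]))
  scale[1] <- 0                                  # no DC
  p <- Re(fft(fft(w) * scale, inverse = TRUE)) / n
  p <- p / sd(p)
  x <- sqrt(1 - white_frac) * p + sqrt(white_frac) * rnorm(n)
  x / sd(x)
}

smooth_positive <- function(n, fs, cutoff = 0.5) {
  lp <- butter(2, cutoff / (fs / 2), type = "low")
  m <- filtfilt(lp, rnorm(n))
  1 + 0.3 * m / max(sd(m), 1e-12)
}

#' Simulate a resting eyes-closed recording with a known alpha peak
#'
#' 1/f background on every channel plus a narrowband alpha oscillation at
#' `iaf`, strongest over the occipital electrodes (O1/O2), amplitude-modulated
#' to mimic waxing-and-waning alpha. The true alpha frequency is returned in
#' the truth manifest.
#'
#' @param iaf Individual alpha frequency, Hz; the estimation band is 7--14 Hz
#'   and values outside it trigger a warning (the estimator will clip).
#' @param alpha_snr Occipital alpha-to-background amplitude ratio in dB;
#'   `-Inf` (or very small) embeds no oscillation.
#' @param duration Seconds (>= 60 recommended for estimation; default 180 s,
#'   the resting-protocol length).
#' @param fs Sample rate, Hz.
#' @param noise_sd Background noise sd, uV.
#' @param montage Channel labels.
#' @param seed Integer seed.
#' @return List with `recording` (an `eeg_recording`, session `"rest"`) and
#'   `truth` (list with `iaf`, `alpha_snr`).
#' @export
simulate_resting <- function(iaf = 10, alpha_snr = 6, duration = 180,
                             fs = 256, noise_sd = 10,
                             montage = default_montage(), seed = 1) {
  if (iaf < 7 || iaf > 14)
    warning("iaf outside the 7-14 Hz estimation band; the estimator will clip")
  set.seed(seed)
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  occ_w <- ifelse(montage %in% c("O1", "O2"), 1,
                  ifelse(montage %in% c("P3", "P4", "P7", "P8"), 0.5, 0.2))
  alpha_amp <- noise_sd * db_to_amp(alpha_snr)
  data <- matrix(0, length(montage), n)
  for (ch in seq_along(montage)) {
    bg <- noise_sd * pink_noise(n, fs)
    al <- if (is.finite(alpha_snr)) {
      alpha_amp * occ_w[ch] * smooth_positive(n, fs) *
        sin(2 * pi * iaf * tt + runif(1, 0, 2 * pi))
    } else 0
    data[ch, ] <- bg + al
  }
  list(recording = new_eeg_recording(data, fs, montage, session = "rest"),
       truth = list(iaf = iaf, alpha_snr = alpha_snr, noise_sd = noise_sd))
}

inject_artifacts <- function(data, fs, montage, artifacts) {
  inventory <- list()
  n <- ncol(data)
  tt <- (seq_len(n) - 1) / fs
  frontal <- which(montage %in% c("Fp1", "Fp2"))
  frontal2 <- which(montage %in% c("F3", "F4", "F7", "F8"))
  temporal <- which(montage %in% c("T7", "T8", "F7", "F8"))
  if (!is.null(artifacts$ocular)) {
    a <- artifacts$ocular
    amp <- a$amplitude %||% 120; k <- a$n %||% 10
    onsets <- sort(runif(k, 1, n / fs - 1))
    for (t0 in onsets) {
      len <- round(0.4 * fs)
      idx <- round(t0 * fs) + seq_len(len)
      blink <- amp * sin(pi * seq_len(len) / len) ^ 2
      data[frontal, idx] <- data[frontal, idx] + rep(blink, each = length(frontal))
      data[frontal2, idx] <- data[frontal2, idx] + 0.4 * rep(blink, each = length(frontal2))
    }
    inventory$ocular <- list(type = "ocular", channels = montage[frontal],
                             onsets = onsets, amplitude = amp)
  }
  if (!is.null(artifacts$muscle)) {
    a <- artifacts$muscle
    amp <- a$amplitude %||% 50; k <- a$n %||% 5
    bpm <- butter(4, c(30, min(100, fs / 2 * 0.95)) / (fs / 2), type = "pass")
    onsets <- sort(runif(k, 1, n / fs - 1))
    for (t0 in onsets) {
      len <- round(0.5 * fs)
      idx <- round(t0 * fs) + seq_len(len)
      burst <- filtfilt(bpm, rnorm(len)); burst <- amp * burst / max(abs(burst))
      ch <- sample(temporal, 1)
      data[ch, idx] <- data[ch, idx] + burst
    }
    inventory$muscle <- list(type = "muscle", onsets = onsets, amplitude = amp)
  }
  if (!is.null(artifacts$line)) {
    amp <- artifacts$line$amplitude %||% 5
    data <- data + matrix(amp * sin(2 * pi * 60 * tt), nrow(data), n, byrow = TRUE)
    inventory$line <- list(type = "line", freq = 60, amplitude = amp)
  }
  if (!is.null(artifacts$pops)) {
    a <- artifacts$pops
    amp <- a$amplitude %||% 500; k <- a$n %||% 2
    onsets <- sort(runif(k, 1, n / fs - 2))
    chs <- sample(seq_along(montage), k, replace = TRUE)
    for (j in seq_len(k)) {
      idx <- round(onsets[j] * fs) + seq_len(round(1 * fs))  # 1-s step offset
      data[chs[j], idx] <- data[chs[j], idx] + amp
    }
    inventory$pops <- list(type = "pop", channels = montage[chs],
                           onsets = onsets, amplitude = amp)
  }
  list(data = data, inventory = inventory)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a stimulation-session recording with known ground truth
#'
#' At every scheduled stimulus onset the component template is added to the
#' montage with per-channel weights and a per-trial latency jitter whose sd
#' is `(1 - itc_level) * 40` ms — `itc_level = 1` means perfectly
#' phase-locked trials, 0 heavy temporal smearing. Background is 1/f plus
#' white noise; optional ocular, muscle, 60-Hz line and electrode-pop
#' artifacts can be injected, all logged in the truth manifest.
#'
#' @param template An `aerp_template` (see [make_template()]).
#' @param schedule A `stimulation_schedule` (see [build_schedule()]).
#' @param itc_level Trial phase-locking level in \[0, 1\].
#' @param noise_sd Background noise sd, uV.
#' @param artifacts Optional list with elements `ocular`, `muscle`, `line`,
#'   `pops` (each a list of parameters), or `NULL` for a clean recording.
#' @param seed Integer seed.
#' @param montage Channel labels.
#' @param channel_weights Named per-channel template weights; defaults to
#'   [default_channel_weights()].
#' @param start_offset First-stimulus delay, s; leaves room for the
#'   pre-stimulus window while keeping the recording at the schedule length.
#' @param session Session tag (`"S0"` or `"Sf"`).
#' @return List with `recording` (an `eeg_recording` carrying the event
#'   markers) and `truth` (components, jitter sd, weights, artifact
#'   inventory).
#' @export
simulate_session <- function(template, schedule, itc_level = 1, noise_sd = 5,
                             artifacts = NULL, seed = 1,
                             montage = default_montage(),
                             channel_weights = NULL, start_offset = 0.5,
                             session = "S0") {
  stopifnot(itc_level >= 0, itc_level <= 1)
  fs <- template$fs
  n <- round(schedule$total * fs)
  last_end <- start_offset + schedule$onsets[length(schedule$onsets)] +
    schedule$stim_duration
  if (last_end > schedule$total)
    stop("schedule overruns the recording duration")
  if (is.null(channel_weights)) channel_weights <- default_channel_weights(montage)
  channel_weights <- channel_weights[montage]
  set.seed(seed)
  data <- matrix(0, length(montage), n)
  for (ch in seq_along(montage))
    data[ch, ] <- noise_sd * pink_noise(n, fs)

  jitter_sd_ms <- (1 - itc_level) * 40
  onset_samples <- round((start_offset + schedule$onsets) * fs) + 1
  n_pre <- sum(template$times < 0)
  tlen <- length(template$wave)
  jitters <- rnorm(length(onset_samples), 0, jitter_sd_ms)
  for (k in seq_along(onset_samples)) {
    i0 <- onset_samples[k] + round(jitters[k] / 1000 * fs) - n_pre
    idx <- i0 + seq_len(tlen) - 1
    keep <- idx >= 1 & idx <= n
    if (!any(keep)) next
    data[, idx[keep]] <- data[, idx[keep]] +
      outer(channel_weights, template$wave[keep])
  }

  inventory <- list()
  if (!is.null(artifacts)) {
    ia <- inject_artifacts(data, fs, montage, artifacts)
    data <- ia$data
    inventory <- ia$inventory
  }
  events <- data.frame(sample = onset_samples,
                       label = rep("stim", length(onset_samples)))
  rec <- new_eeg_recording(data, fs, montage, events, session)
  truth <- list(components = template$components,
                template = template,
                channel_weights = channel_weights,
                itc_level = itc_level, jitter_sd_ms = jitter_sd_ms,
                jitters_ms = jitters, noise_sd = noise_sd,
                artifacts = inventory, seed = seed)
  list(recording = rec, truth = truth)
}
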