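#' Remove the per-channel baseline (DC offset)
#'
#' Subtracts each channel's mean over the whole recording.
#'
#' @param rec An `eeg_recording`.
#' @return The recording with zero-mean channels.
#' @export
remove_baseline <- function(rec) {
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) IIR Butterworth band-pass. `order` is the
#' analog prototype order of the band-pass (an order-8 band-pass is realized
#' from a 4-pole low-pass prototype); forward-backward application doubles
#' the effective order and cancels the phase response, preserving component
#' latencies.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band edges, Hz (defaults 0.1--100).
#' @param order Band-pass filter order (even).
#' @return Filtered recording.
#' @export
bandpass <- function(rec, low = 0.1, high = 100, order = 8) {
  if (high >= rec$fs / 2) stop("upper band edge must be below the Nyquist frequency")
  stopifnot(low > 0, low < high, order %% 2 == 0)
  bp <- butter(order / 2, c(low, high) / (rec$fs / 2), type = "pass")
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- filtfilt(bp, rec$data[ch, ])
  rec
}

#' Reject the 60-Hz line component
#'
#' Zero-phase second-order Butterworth band-stop at 58--62 Hz.
#'
#' @param rec An `eeg_recording` with `fs > 120`.
#' @param order Band-stop order per section.
#' @return Filtered recording.
#' @export
notch60 <- function(rec, order = 2) {
  if (rec$fs <= 120) stop("sampling rate too low for a 60-Hz notch")
  ns <- butter(order, c(58, 62) / (rec$fs / 2), type = "stop")
  for (ch in seq_len(nrow(rec$data)))
    rec$data[ch, ] <- filtfilt(ns, rec$data[ch, ])
  rec
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one epoch per event, `pre` ms before to `post` ms after onset
#' (default -200 to +800 ms, i.e. 256 samples at 256 Hz). Events whose
#' window falls partially outside the recording are dropped and logged.
#' Optionally subtracts the pre-stimulus mean per epoch and channel.
#'
#' @param rec An `eeg_recording` with events.
#' @param events Optional event data frame (`sample`, `label`); defaults to
#'   the recording's own events.
#' @param pre,post Window extent before/after onset, ms.
#' @param baseline_correct Subtract the pre-stimulus mean (default `TRUE`).
#' @return An `epoch_set`: `epochs` (trials x channels x samples array, uV),
#'   `times` (ms), `fs`, `channels`, `dropped` (indices of dropped events).
#' @export
segment_epochs <- function(rec, events = NULL, pre = 200, post = 800,
                           baseline_correct = TRUE) {
  if (is.null(events)) events <- rec$events
  if (is.null(events) || nrow(events) == 0) stop("no events to segment on")
  fs <- rec$fs
  n_pre <- round(pre * fs / 1000)
  n_tot <- round((pre + post) * fs / 1000)
  times <- (seq_len(n_tot) - 1 - n_pre) / fs * 1000
  n <- ncol(rec$data)
  starts <- events$sample - n_pre
  usable <- starts >= 1 & (starts + n_tot - 1) <= n
  dropped <- which(!usable)
  if (!any(usable)) stop("no usable events: every epoch window falls outside the recording")
  keep <- which(usable)
  ep <- array(0, dim = c(length(keep), nrow(rec$data), n_tot))
  for (j in seq_along(keep)) {
    idx <- starts[keep[j]] + seq_len(n_tot) - 1
    seg <- rec$data[, idx, drop = FALSE]
    if (baseline_correct && n_pre > 0)
      seg <- seg - rowMeans(seg[, seq_len(n_pre), drop = FALSE])
    ep[j, , ] <- seg
  }
  structure(list(epochs = ep, times = times, fs = fs,
                 channels = rec$channels, dropped = dropped),
            class = "epoch_set")
}

#' Run the full six-step cleaning chain and segment
#'
#' Fixed order: (1) baseline removal, (2) 0.1--100 Hz Butterworth band-pass,
#' (3) 60-Hz notch, (4) artifact subspace reconstruction, (5) wavelet-ICA
#' removal of stationary artifacts, (6) epoch segmentation. Steps 4 and 5
#' can be disabled for recordings known to be artifact-free.
#'
#' @param rec An `eeg_recording` with events.
#' @param asr,wica Logical switches for steps 4 and 5.
#' @param cutoff_k ASR rejection threshold (see [asr_clean()]).
#' @param pre,post Segmentation window, ms.
#' @param seed Seed for the ICA initialization.
#' @return List with `epochs` (an `epoch_set`) and `report` (per-step
#'   `cleaning_report` entries in execution order).
#' @export
preprocess_recording <- function(rec, asr = TRUE, wica = TRUE,
                                 cutoff_k = 20, pre = 200, post = 800,
                                 seed = 1) {
  report <- list()
  rec <- remove_baseline(rec)
  report$baseline <- list(step = 1, op = "baseline removal")
  rec <- bandpass(rec)
  report$bandpass <- list(step = 2, op = "band-pass 0.1-100 Hz, Butterworth order 8")
  rec <- notch60(rec)
  report$notch <- list(step = 3, op = "60-Hz notch, Butterworth order 2")
  if (asr) {
    out <- asr_clean(rec, cutoff_k = cutoff_k)
    rec <- out$recording
    report$asr <- c(list(step = 4, op = "artifact subspace reconstruction"),
                    out$report)
  }
  if (wica) {
    out <- remove_stationary(rec, seed = seed)
    rec <- out$recording
    report$wica <- c(list(step = 5, op = "wavelet-ICA stationary-artifact removal"),
                     out$report)
  }
  ep <- segment_epochs(rec, pre = pre, post = post)
  report$segment <- list(step = 6, op = "epoch segmentation",
                         n_epochs = dim(ep$epochs)[1],
                         dropped = ep$dropped)
  list(epochs = ep, report = report)
}
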