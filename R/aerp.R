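#' @importFrom pracma trapz
NULL

#' Estimate the individual alpha frequency (IAF)
#'
#' Welch power spectral densities of the occipital channels O1 and O2 are
#' averaged and the peak of the mean spectrum within the 7--14 Hz band is
#' returned. The FFT grid is refined to at least 0.0625-Hz resolution. A
#' peak less than twice the in-band median power triggers a
#' low-prominence warning.
#'
#' @param rec A resting `eeg_recording` containing O1 and O2, >= 60 s.
#' @param band Search band, Hz.
#' @return IAF in Hz, with attribute `prominence` (peak / median power).
#' @export
estimate_iaf <- function(rec, band = c(7, 14)) {
  occ <- c("O1", "O2")
  if (!all(occ %in% rec$channels)) stop("occipital channels O1/O2 missing")
  if (ncol(rec$data) < 60 * rec$fs) stop("resting recording must be at least 60 s")
  nperseg <- round(8 * rec$fs)
  nfft <- 2 ^ ceiling(log2(16 * rec$fs))
  ps <- lapply(occ, function(ch)
    welch_psd(rec$data[ch, ], rec$fs, nperseg = nperseg, nfft = nfft))
  psd <- (ps[[1]]$psd + ps[[2]]$psd) / 2
  f <- ps[[1]]$freq
  in_band <- f >= band[1] & f <= band[2]
  pk <- which.max(psd[in_band])
  prominence <- psd[in_band][pk] / stats::median(psd[in_band])
  if (prominence < 2)
    warning("low alpha-peak prominence; IAF estimate may be unreliable")
  structure(f[in_band][pk], prominence = prominence)
}

#' Average epochs into an evoked waveform
#'
#' Arithmetic mean across trials, per channel and sample.
#'
#' @param ep An `epoch_set` with >= 1 trial.
#' @return Channels x samples matrix (uV) with attribute `times` (ms).
#' @export
average_epochs <- function(ep) {
  if (is.null(dim(ep$epochs)) || dim(ep$epochs)[1] < 1) stop("empty epoch set")
  avg <- apply(ep$epochs, c(2, 3), mean)
  rownames(avg) <- ep$channels
  attr(avg, "times") <- ep$times
  avg
}

#' Inter-trial coherence around the individual alpha frequency
#'
#' Per channel, each trial's epoch is reduced to a unit complex phasor of
#' the band-limited (IAF +/- `halfwidth` Hz) analytic signal over the
#' post-stimulus window, and the ITC is the magnitude of the phasor mean
#' across trials: 1 for perfectly phase-locked trials, near 0 for random
#' phase. The default averages the per-sample phasor-mean magnitude over
#' the window; `method = "peak"` instead samples the phase at each trial's
#' envelope peak (noisier on low-amplitude trials).
#'
#' @param ep An `epoch_set`.
#' @param iaf Band center, Hz.
#' @param halfwidth Half band width, Hz (default 2).
#' @param method `"persample"` or `"peak"`.
#' @return Named per-channel numeric vector in \[0, 1\].
#' @export
compute_itc <- function(ep, iaf = 10, halfwidth = 2,
                        method = c("persample", "peak")) {
  method <- match.arg(method)
  band <- c(iaf - halfwidth, iaf + halfwidth)
  if (band[1] <= 0 || band[2] >= ep$fs / 2)
    stop("ITC band must lie inside (0, fs/2)")
  dims <- dim(ep$epochs)
  n_trial <- dims[1]; n_ch <- dims[2]
  if (n_trial == 1) {
    warning("single trial: ITC is degenerately 1")
    return(stats::setNames(rep(1, n_ch), ep$channels))
  }
  post <- which(ep$times >= 0)
  itc <- numeric(n_ch)
  for (ch in seq_len(n_ch)) {
    if (method == "peak") {
      phasors <- complex(real = numeric(n_trial), imaginary = numeric(n_trial))
      for (tr in seq_len(n_trial)) {
        a <- band_analytic(ep$epochs[tr, ch, ], ep$fs, band)[post]
        pk <- which.max(Mod(a))
        phasors[tr] <- a[pk] / max(Mod(a[pk]), 1e-20)
      }
      itc[ch] <- Mod(mean(phasors))
    } else {
      U <- matrix(0 + 0i, n_trial, length(post))
      for (tr in seq_len(n_trial)) {
        a <- band_analytic(ep$epochs[tr, ch, ], ep$fs, band)[post]
        U[tr, ] <- a / pmax(Mod(a), 1e-20)
      }
      itc[ch] <- mean(Mod(colMeans(U)))
    }
  }
  stats::setNames(pmin(itc, 1), ep$channels)
}

#' Weight an evoked waveform by ITC and IAF
#'
#' Each channel's waveform is multiplied by its inter-trial coherence (to
#' suppress random peaks relative to phase-locked components) and by a
#' channel-independent alpha-normalization scalar
#' `reference_iaf / iaf` that compensates demographic IAF differences
#' (weights are 1 at the canonical 10-Hz alpha peak).
#'
#' @param avg Channels x samples waveform from [average_epochs()].
#' @param itc Per-channel ITC in \[0, 1\].
#' @param iaf Participant IAF, Hz (`NULL` for no alpha normalization).
#' @param reference_iaf Reference alpha frequency, Hz.
#' @param session Session tag.
#' @return An `aerp_result`: `waveform` (weighted), `times`, `itc`, `iaf`,
#'   `weights`, `session`, `channels`.
#' @export
weight_aerp <- function(avg, itc, iaf = NULL, reference_iaf = 10,
                        session = "S0") {
  if (any(itc < 0 | itc > 1)) stop("ITC values must lie in [0, 1]")
  iaf_w <- if (is.null(iaf)) 1 else reference_iaf / as.numeric(iaf)
  w <- itc * iaf_w
  structure(list(waveform = avg * w, times = attr(avg, "times"),
                 itc = itc, iaf = if (is.null(iaf)) NA_real_ else as.numeric(iaf),
                 weights = w, session = session, channels = rownames(avg)),
            class = "aerp_result")
}

#' Grand average of AERP results across participants
#'
#' Unweighted mean of the (already ITC/IAF-weighted) per-participant
#' waveforms, per channel and sample.
#'
#' @param results List of `aerp_result` objects sharing montage and window.
#' @param group,session Labels carried into the output.
#' @return Channels x samples matrix with attributes `times`, `group`,
#'   `session`.
#' @export
grand_average <- function(results, group = NULL, session = NULL) {
  stopifnot(length(results) >= 1)
  ref <- results[[1]]
  for (r in results) {
    if (!identical(r$channels, ref$channels) ||
        !isTRUE(all.equal(r$times, ref$times)))
      stop("incompatible montage or time axis across results")
  }
  ga <- Reduce(`+`, lapply(results, `[[`, "waveform")) / length(results)
  rownames(ga) <- ref$channels
  attr(ga, "times") <- ref$times
  attr(ga, "group") <- group
  attr(ga, "session") <- session %||% ref$session
  ga
}

#' AUC of the grand-average difference between sessions
#'
#' Per channel, the signed trapezoidal integral over the full epoch window
#' of the final-minus-initial grand-average difference (Sf - S0), in
#' uV*ms. The magnitude ranks channels: `auc_max` is the largest |AUC| and
#' `auc_ch` the channel attaining it (earliest channel on ties).
#'
#' @param ga_sf,ga_s0 Grand averages with identical channel and time axes.
#' @param group Group label.
#' @return An `auc_comparison`: `auc` (signed, per channel), `auc_max`,
#'   `auc_ch`, `group`, `sessions`.
#' @export
auc_difference <- function(ga_sf, ga_s0, group = NULL) {
  if (!identical(rownames(ga_sf), rownames(ga_s0)) ||
      !isTRUE(all.equal(attr(ga_sf, "times"), attr(ga_s0, "times"))))
    stop("grand averages have incompatible axes")
  times <- attr(ga_sf, "times")
  d <- ga_sf - ga_s0
  auc <- apply(d, 1, function(y) trapz(times, y))
  i <- which.max(abs(auc))
  structure(list(auc = auc, auc_max = abs(auc[[i]]), auc_ch = names(auc)[i],
                 group = group, sessions = c("S0", "Sf")),
            class = "auc_comparison")
}

#' Detect evoked-component peaks in search windows
#'
#' For each named window the extremum of the expected polarity is located:
#' components named `N*` are minima, `P*` maxima. On ties the earliest
#' extremum wins (a flat zero waveform reports amplitude 0 at the window
#' start).
#'
#' @param wave Numeric waveform (uV) or one row of a grand average.
#' @param times Time axis, ms; taken from `attr(wave, "times")` if absent.
#' @param windows Named list of `c(from, to)` ms search windows, e.g.
#'   `list(N1 = c(100, 200), P3 = c(280, 420))`.
#' @return Data frame `component`, `amplitude` (uV), `latency` (ms).
#' @export
detect_components <- function(wave, windows, times = NULL) {
  if (is.null(times)) times <- attr(wave, "times")
  stopifnot(!is.null(times), length(times) == length(wave))
  out <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    if (w[1] < min(times) || w[2] > max(times))
      stop("search window outside the epoch")
    idx <- which(times >= w[1] & times <= w[2])
    seg <- wave[idx]
    pick <- if (startsWith(nm, "N")) which.min(seg) else which.max(seg)
    data.frame(component = nm, amplitude = seg[pick],
               latency = times[idx][pick], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
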