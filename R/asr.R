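#' Artifact subspace reconstruction (simplified operator)
#'
#' Sliding-window principal-subspace cleaning of transient, high-variance
#' artifacts (muscle bursts, motion, electrode pops). A principal-component
#' basis and per-component spread are learned from an artifact-light
#' calibration segment; stretches where a component's sliding-window RMS
#' exceeds `cutoff_k` times the calibration spread are removed (with half-
#' window dilation to cover artifact edges) and the data are reconstructed
#' from the retained subspace. Clean data passes through unchanged;
#' `cutoff_k = Inf` is the identity transform.
#'
#' @param rec An `eeg_recording`.
#' @param calibration Optional `eeg_recording` (or channels x samples
#'   matrix) of clean data, >= 30 s. By default the quietest `calib_s`
#'   seconds of `rec` are found by a sliding-RMS search.
#' @param cutoff_k Rejection threshold in calibration standard deviations.
#' @param window_s Analysis window length, s.
#' @param calib_s Length of the auto-selected calibration segment, s.
#' @return List with `recording` (cleaned) and `report` (component
#'   rejections, variance removed, parameters used).
#' @export
asr_clean <- function(rec, calibration = NULL, cutoff_k = 20,
                      window_s = 0.5, calib_s = 60) {
  fs <- rec$fs
  X <- rec$data
  n <- ncol(X)
  if (is.null(calibration)) {
    calib_s <- min(calib_s, floor(n / fs))
    wlen <- round(calib_s * fs)
    step <- round(fs)  # 1-s stride
    starts <- seq(1, n - wlen + 1, by = step)
    tot <- colSums(X ^ 2)
    ctot <- c(0, cumsum(tot))
    rms_w <- vapply(starts, function(s) ctot[s + wlen] - ctot[s], numeric(1))
    s0 <- starts[which.min(rms_w)]
    C <- X[, s0 + seq_len(wlen) - 1, drop = FALSE]
  } else {
    C <- if (inherits(calibration, "eeg_recording")) calibration$data else calibration
    if (ncol(C) < 30 * fs)
      stop("calibration segment must be at least 30 s long")
  }
  C <- C - rowMeans(C)
  eg <- eigen(stats::cov(t(C)), symmetric = TRUE)
  V <- eg$vectors
  sd_cal <- sqrt(pmax(eg$values, 1e-12))

  wlen <- round(window_s * fs)
  var_in <- sum(X ^ 2)
  rejected <- 0L
  if (is.finite(cutoff_k)) {
    S <- crossprod(V, X)
    # per-component centered sliding-window RMS (stride 1 via cumulated sums);
    # flagged stretches are dilated by half a window to cover artifact edges
    half <- floor(wlen / 2)
    for (i in seq_len(nrow(S))) {
      cs <- c(0, cumsum(S[i, ] ^ 2))
      lo <- pmax(seq_len(n) - half, 0)
      hi <- pmin(seq_len(n) + half, n)
      run_ms <- (cs[hi + 1] - cs[lo + 1]) / (hi - lo)
      bad <- run_ms > (cutoff_k * sd_cal[i]) ^ 2
      if (any(bad)) {
        bad_idx <- which(bad)
        dil <- unique(unlist(lapply(bad_idx, function(s)
          max(1, s - half):min(n, s + half))))
        S[i, dil] <- 0
        rejected <- rejected + 1L
      }
    }
    X <- V %*% S
    rownames(X) <- rec$channels
  }
  rec$data <- X
  list(recording = rec,
       report = list(components_rejected = rejected,
                     variance_removed_pct = 100 * (1 - sum(X ^ 2) / var_in),
                     cutoff_k = cutoff_k, window_s = window_s))
}
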