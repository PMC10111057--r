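#' Default 16-channel 10/20 montage
#'
#' Scalp channel labels for the 16-channel recording setup (10/20 International
#' System, reference A1 and ground Cz excluded from the data channels).
#'
#' @return Character vector of 16 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4",
    "T7", "T8", "P3", "P4", "P7", "P8", "O1", "O2")
}

#' Default evoked-response channel weights
#'
#' Spatial weighting used when projecting a single-trace component template
#' onto the montage: fronto-central emphasis, decaying toward temporal,
#' parietal and occipital sites.
#'
#' @param montage Character vector of channel labels.
#' @return Named numeric vector of weights in \[0, 1\].
#' @export
default_channel_weights <- function(montage = default_montage()) {
  w <- rep(0.4, length(montage))
  names(w) <- montage
  w[names(w) %in% c("F3", "F4", "C3", "C4")] <- 1
  w[names(w) %in% c("Fp1", "Fp2", "F7", "F8")] <- 0.8
  w[names(w) %in% c("T7", "T8")] <- 0.5
  w[names(w) %in% c("P3", "P4", "P7", "P8")] <- 0.4
  w[names(w) %in% c("O1", "O2")] <- 0.3
  w
}
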