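# sym4 (least-asymmetric, 8-tap) orthogonal wavelet filters
SYM4_DEC_LO <- c(-0.07576571478927333, -0.02963552764599851,
                 0.49761866763201545, 0.8037387518059161,
                 0.29785779560527736, -0.09921954357684722,
                 -0.012603967262037833, 0.0322231006040427)
SYM4_DEC_HI <- rev(SYM4_DEC_LO) * rep(c(-1, 1), 4)

dwt_step <- function(x) {
  n <- length(x)
  L <- length(SYM4_DEC_LO)
  h <- rev(SYM4_DEC_LO); g <- rev(SYM4_DEC_HI)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  for (k in seq_len(half)) {
    idx <- ((2 * (k - 1) + 0:(L - 1) - 3) %% n) + 1
    seg <- x[idx]
    a[k] <- sum(h * seg)
    d[k] <- sum(g * seg)
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  n <- 2 * length(a)
  L <- length(SYM4_DEC_LO)
  h <- rev(SYM4_DEC_LO); g <- rev(SYM4_DEC_HI)
  x <- numeric(n)
  for (k in seq_along(a)) {
    idx <- ((2 * (k - 1) + 0:(L - 1) - 3) %% n) + 1
    x[idx] <- x[idx] + h * a[k] + g * d[k]
  }
  x
}

#' Periodized sym4 discrete wavelet transform
#'
#' Multi-level pyramid decomposition with the orthogonal sym4 wavelet and
#' periodic boundary handling. The input is zero-padded to a multiple of
#' `2^levels`; [dwt_inverse()] restores the original length.
#'
#' @param x Numeric vector.
#' @param levels Decomposition depth.
#' @return List with `approx` (coarsest approximation), `details` (list of
#'   detail coefficients, finest first), `n` (original length).
#' @export
dwt_forward <- function(x, levels = 5) {
  n <- length(x)
  block <- 2 ^ levels
  npad <- ceiling(n / block) * block
  if (npad > n) x <- c(x, numeric(npad - n))
  # the coarsest band must stay at least one filter long, otherwise the
  # periodized filter wraps onto itself and orthogonality is lost
  levels <- min(levels, floor(log2(npad / length(SYM4_DEC_LO))) + 1)
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(a)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, n = n)
}

#' Inverse of [dwt_forward()]
#'
#' @param w Decomposition as returned by [dwt_forward()].
#' @return Numeric vector of the original length.
#' @export
dwt_inverse <- function(w) {
  a <- w$approx
  for (l in rev(seq_along(w$details)))
    a <- idwt_step(a, w$details[[l]])
  a[seq_len(w$n)]
}

excess_kurtosis <- function(x) {
  m <- mean(x); v <- mean((x - m) ^ 2)
  if (v < 1e-20) return(0)
  mean((x - m) ^ 4) / v ^ 2 - 3
}

lowfreq_power_fraction <- function(x, fs, cutoff = 4) {
  n <- length(x)
  p <- Mod(fft(x - mean(x))[seq_len(floor(n / 2))]) ^ 2
  f <- (seq_len(floor(n / 2)) - 1) * fs / n
  sum(p[f < cutoff]) / max(sum(p), 1e-20)
}

#' Symmetric FastICA
#'
#' Independent component analysis by the fixed-point FastICA iteration with
#' the tanh contrast and symmetric decorrelation, seeded deterministic
#' initialization.
#'
#' @param X Channels x samples matrix.
#' @param n_comp Number of components (default: number of channels).
#' @param seed Seed for the orthonormal random initialization.
#' @param max_iter,tol Iteration controls. When the tolerance is not met
#'   within `max_iter` the last (decorrelated, hence still valid) rotation
#'   is returned with `converged = FALSE`; directions in a near-Gaussian
#'   subspace have no preferred rotation and oscillate without affecting
#'   the non-Gaussian components of interest.
#' @return List with `S` (components x samples), `A` (mixing, channels x
#'   components), `W` (unmixing in whitened space), `center`, `converged`.
#'   `NULL` if the data are rank-deficient.
#' @export
fast_ica <- function(X, n_comp = nrow(X), seed = 1, max_iter = 200,
                     tol = 1e-5) {
  ctr <- rowMeans(X)
  Xc <- X - ctr
  eg <- eigen(Xc %*% t(Xc) / ncol(Xc), symmetric = TRUE)
  if (any(eg$values < 1e-10 * eg$values[1])) return(NULL)  # rank deficient
  K <- diag(1 / sqrt(eg$values[seq_len(n_comp)])) %*%
    t(eg$vectors[, seq_len(n_comp), drop = FALSE])
  Z <- K %*% Xc
  set.seed(seed)
  W <- matrix(rnorm(n_comp ^ 2), n_comp)
  sym_decorr <- function(W) {
    sv <- eigen(W %*% t(W), symmetric = TRUE)
    sv$vectors %*% diag(1 / sqrt(pmax(sv$values, 1e-16))) %*%
      t(sv$vectors) %*% W
  }
  W <- sym_decorr(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(U)
    W1 <- G %*% t(Z) / ncol(Z) - diag(rowMeans(1 - G ^ 2)) %*% W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  S <- W %*% Z
  A <- eg$vectors[, seq_len(n_comp), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(n_comp)])) %*% t(W)
  list(S = S, A = A, W = W, center = ctr, converged = converged)
}

#' Remove stationary artifacts by wavelet-enhanced ICA
#'
#' Hybrid cleaning of ocular/cardiac-type stationary artifacts: the
#' recording is decomposed into independent components; components whose
#' excess kurtosis or low-frequency (< 4 Hz) power fraction exceeds the
#' thresholds are wavelet-thresholded (sym4, `levels` levels, per-level
#' robust universal thresholds) and the reconstructed
#' large-coefficient artifact part is subtracted, preserving the underlying
#' low-amplitude activity; the cleaned components are remixed.
#'
#' @param rec An `eeg_recording` (>= 2 channels, >= 10 s).
#' @param n_components Number of independent components (default: all).
#' @param seed ICA initialization seed.
#' @param kurt_threshold Excess-kurtosis flag threshold.
#' @param lowfreq_threshold Low-frequency power-fraction flag threshold.
#' @param levels Wavelet decomposition depth.
#' @return List with `recording` and `report` (flagged components, variance
#'   removed, `degraded` flag when the decomposition fails and the input is
#'   returned unchanged).
#' @export
remove_stationary <- function(rec, n_components = NULL, seed = 1,
                              kurt_threshold = 5, lowfreq_threshold = 0.6,
                              levels = 5) {
  if (nrow(rec$data) < 2) stop("at least 2 channels required")
  if (ncol(rec$data) < 10 * rec$fs) stop("recording must be at least 10 s long")
  if (is.null(n_components)) n_components <- nrow(rec$data)
  ica <- fast_ica(rec$data, n_components, seed = seed)
  if (is.null(ica)) {
    warning("ICA decomposition failed (rank-deficient data); returning input unchanged (degraded mode)")
    return(list(recording = rec,
                report = list(degraded = TRUE, flagged = integer(0))))
  }
  S <- ica$S
  flagged <- integer(0)
  for (i in seq_len(nrow(S))) {
    k <- excess_kurtosis(S[i, ])
    lf <- lowfreq_power_fraction(S[i, ], rec$fs)
    if (k > kurt_threshold || lf > lowfreq_threshold) {
      flagged <- c(flagged, i)
      w <- dwt_forward(S[i, ], levels = levels)
      nsig <- length(S[i, ])
      # per-level robust thresholds: only coefficients that are outliers
      # relative to their own level's spread count as artifact, so ordinary
      # slow activity in the coarse levels is preserved
      keep_large <- function(v) {
        thr <- mad(v) * sqrt(2 * log(nsig))
        ifelse(abs(v) > thr, v, 0)
      }
      w$approx <- keep_large(w$approx)
      w$details <- lapply(w$details, keep_large)
      artifact <- dwt_inverse(w)
      S[i, ] <- S[i, ] - artifact
    }
  }
  var_in <- sum((rec$data - rowMeans(rec$data)) ^ 2)
  clean <- ica$A %*% S + ica$center
  rownames(clean) <- rec$channels
  rec$data <- clean
  list(recording = rec,
       report = list(degraded = FALSE, flagged = flagged,
                     n_components = n_components,
                     variance_removed_pct =
                       100 * (1 - sum((rec$data - rowMeans(rec$data)) ^ 2) / var_in)))
}
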