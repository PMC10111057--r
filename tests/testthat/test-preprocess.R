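make_rec <- function(data, fs = 256, events = NULL) {
  tinnaerp:::new_eeg_recording(data, fs,
                               default_montage()[seq_len(nrow(data))], events)
}

test_that("baseline removal zeroes per-channel means", {
  n <- 256 * 5
  data <- rbind(rep(5, n),                        # constant channel
                sin(2 * pi * 7 * (1:n) / 256),    # zero-mean sine
                rnorm(n, 3, 2))
  rec <- remove_baseline(make_rec(data))
  expect_true(all(abs(rowMeans(rec$data)) < 1e-9))
  expect_true(all(rec$data[1, ] == 0))
  expect_equal(rec$data[2, ], data[2, ], tolerance = 1e-9)
})

test_that("band-pass keeps the EEG band and rejects drift and HF", {
  fs <- 256; t <- seq(0, 30, by = 1 / fs); n <- length(t)
  mid <- 2000:(n - 2000)
  s10 <- sin(2 * pi * 10 * t)
  rec <- bandpass(make_rec(rbind(s10)))
  expect_equal(stats::sd(rec$data[1, mid]) / stats::sd(s10[mid]), 1,
               tolerance = 0.05)
  drift <- sin(2 * pi * 0.01 * t)
  recd <- bandpass(make_rec(rbind(drift)))
  expect_lt(20 * log10(max(abs(recd$data[1, mid]))), -20)
  set.seed(1)
  wn <- rnorm(n)
  recw <- bandpass(make_rec(rbind(wn)))
  expect_lt(band_power(recw$data[1, ], fs, c(110, 128)) /
              band_power(recw$data[1, ], fs, c(0, 128)), 0.01)
  expect_error(bandpass(make_rec(rbind(wn)), high = 130), "Nyquist")
})

test_that("the 60-Hz notch is narrow and deep", {
  fs <- 256; t <- seq(0, 20, by = 1 / fs); mid <- 1500:(length(t) - 1500)
  r60 <- notch60(make_rec(rbind(sin(2 * pi * 60 * t))))
  expect_lt(stats::sd(r60$data[1, mid]) / stats::sd(sin(2 * pi * 60 * t)[mid]), 0.10)
  r10 <- notch60(make_rec(rbind(sin(2 * pi * 10 * t))))
  expect_equal(stats::sd(r10$data[1, mid]) / stats::sd(sin(2 * pi * 10 * t)[mid]),
               1, tolerance = 0.02)
  # removes the simulated line artifact below the noise floor
  sch <- build_schedule(20, 1, 2)
  flat <- make_template(aerp_components("tinnitus")[0, ])
  ss <- simulate_session(flat, sch, noise_sd = 3, seed = 8,
                         artifacts = list(line = list(amplitude = 10)))
  cln <- notch60(ss$recording)
  ps <- welch_psd(cln$data[1, ], 256, nperseg = 1024)
  at60 <- ps$psd[which.min(abs(ps$freq - 60))]
  floor_near <- stats::median(ps$psd[ps$freq > 45 & ps$freq < 55])
  expect_lt(at60, floor_near)
})

test_that("zero-phase filtering leaves component latencies in place", {
  tpl <- make_template(aerp_components("control"))
  rec <- make_rec(matrix(rep(tpl$wave, 4), nrow = 4, byrow = TRUE))
  fl <- notch60(bandpass(rec))
  expect_lte(abs(which.max(fl$data[1, ]) - which.max(tpl$wave)), 1)
  expect_lte(abs(which.min(fl$data[2, ]) - which.min(tpl$wave)), 1)
})

test_that("segmentation yields protocol-sized epochs and drops boundary events", {
  sch <- build_schedule(50, 1, 2)
  tpl <- make_template(aerp_components("tinnitus"))
  ss <- simulate_session(tpl, sch, noise_sd = 1, seed = 9)
  ep <- segment_epochs(ss$recording)
  expect_equal(dim(ep$epochs)[1], 50)
  expect_equal(dim(ep$epochs)[3], 256)   # (0.2 + 0.8) s x 256 Hz
  expect_length(ep$dropped, 0)
  # an event too close to the recording start is dropped and logged
  ev <- rbind(data.frame(sample = 10, label = "stim"), ss$recording$events)
  ep2 <- segment_epochs(ss$recording, events = ev)
  expect_equal(dim(ep2$epochs)[1], 50)
  expect_equal(ep2$dropped, 1)
  short <- make_rec(matrix(0, 2, 100),
                    events = data.frame(sample = 5, label = "stim"))
  expect_error(segment_epochs(short), "usable")
})

test_that("ASR removes electrode pops and passes clean data through", {
  sch <- build_schedule(50, 1, 2)
  tpl <- make_template(aerp_components("tinnitus"))
  ss <- simulate_session(tpl, sch, itc_level = 0.9, noise_sd = 5, seed = 11,
                         artifacts = list(pops = list(n = 2, amplitude = 500)))
  rec <- remove_baseline(ss$recording)
  out <- asr_clean(rec, cutoff_k = 20)
  for (ch in unique(ss$truth$artifacts$pops$channels)) {
    before <- max(abs(rec$data[ch, ]))
    after <- max(abs(out$recording$data[ch, ]))
    expect_lt(after, 0.2 * before)  # >= 80% peak reduction
  }
  clean <- remove_baseline(simulate_session(tpl, sch, itc_level = 0.9,
                                            noise_sd = 5, seed = 12)$recording)
  o2 <- asr_clean(clean, cutoff_k = 20)
  expect_equal(stats::sd(o2$recording$data) / stats::sd(clean$data), 1,
               tolerance = 0.05)
  oInf <- asr_clean(clean, cutoff_k = Inf)
  expect_equal(oInf$recording$data, clean$data)
  expect_error(asr_clean(clean, calibration = clean$data[, 1:1000]), "30 s")
})

test_that("wavelet-ICA removes ocular activity and preserves occipital alpha", {
  # resting background with true alpha plus a frontal blink train built here
  r <- simulate_resting(iaf = 10, alpha_snr = 6, duration = 60, seed = 13)
  rec <- r$recording
  fs <- rec$fs; n <- ncol(rec$data)
  set.seed(14)
  blink <- function() {
    len <- round(0.4 * fs)
    120 * sin(pi * seq_len(len) / len) ^ 2
  }
  for (t0 in sort(runif(15, 1, 58))) {
    idx <- round(t0 * fs) + seq_len(round(0.4 * fs))
    for (ch in c("Fp1", "Fp2")) rec$data[ch, idx] <- rec$data[ch, idx] + blink()
    for (ch in c("F3", "F4")) rec$data[ch, idx] <- rec$data[ch, idx] + 0.4 * blink()
  }
  rec <- remove_baseline(rec)
  out <- remove_stationary(rec, seed = 1)
  expect_false(out$report$degraded)
  expect_gt(length(out$report$flagged), 0)
  lf_before <- band_power(rec$data["Fp1", ], fs, c(0.2, 4))
  lf_after <- band_power(out$recording$data["Fp1", ], fs, c(0.2, 4))
  expect_lt(lf_after / lf_before, 0.5)   # >= 50% low-frequency power reduction
  a_before <- band_power(rec$data["O1", ], fs, c(8, 12))
  a_after <- band_power(out$recording$data["O1", ], fs, c(8, 12))
  expect_equal(a_after / a_before, 1, tolerance = 0.15)
})

test_that("wavelet-ICA passes artifact-free data through and degrades on rank deficiency", {
  sch <- build_schedule(20, 1, 2)
  tpl <- make_template(aerp_components("tinnitus"))
  clean <- remove_baseline(simulate_session(tpl, sch, itc_level = 0.9,
                                            noise_sd = 5, seed = 15)$recording)
  out <- remove_stationary(clean, seed = 1)
  expect_equal(stats::sd(out$recording$data) / stats::sd(clean$data), 1,
               tolerance = 0.10)
  dup <- clean
  dup$data[2, ] <- dup$data[1, ]  # duplicate channel: rank-deficient
  expect_warning(o2 <- remove_stationary(dup, seed = 1), "degraded")
  expect_true(o2$report$degraded)
  expect_equal(o2$recording$data, dup$data)
})

test_that("the full six-step chain recovers the embedded template within 20%", {
  sch <- build_schedule(50, 1, 2)
  tpl <- make_template(aerp_components("tinnitus"))
  ss <- simulate_session(tpl, sch, itc_level = 1, noise_sd = 2, seed = 21,
                         artifacts = list(ocular = list(n = 25, amplitude = 120),
                                          line = list(amplitude = 8),
                                          pops = list(n = 2, amplitude = 400)))
  out <- preprocess_recording(ss$recording, seed = 1)
  expect_equal(vapply(out$report, `[[`, numeric(1), "step"),
               c(baseline = 1, bandpass = 2, notch = 3, asr = 4, wica = 5,
                 segment = 6))
  avg <- average_epochs(out$epochs)
  w <- ss$truth$channel_weights
  # joint amplitude-recovery factor of the multi-channel template
  truth_mat <- outer(w, tpl$wave)
  scale <- sum(avg * truth_mat) / sum(truth_mat ^ 2)
  expect_equal(scale, 1, tolerance = 0.20)
})

test_that("the sym4 transform matches an independent oracle and reconstructs", {
  # single-level coefficients frozen from an independent wavelet implementation
  v <- sin(1:16)
  st <- tinnaerp:::dwt_step(v)
  expect_equal(st$a,
    c(1.199071915723, -1.195015937828, -0.141204635072, 1.303262524673,
      -0.943492518594, -0.517999670835, 1.238024748488, 0.222512928808),
    tolerance = 1e-9)
  expect_equal(st$d,
    c(-0.550089937829, 0.047598438804, 0.285624398367, -0.263508617869,
      -0.066307842909, 0.318696215999, -0.257035013606, 0.005116918610),
    tolerance = 1e-9)
  set.seed(2)
  for (len in c(64, 100, 321)) {
    x <- rnorm(len)
    w <- dwt_forward(x, levels = 5)
    expect_equal(dwt_inverse(w), x, tolerance = 1e-9)
  }
})
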