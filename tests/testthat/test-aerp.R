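test_that("IAF estimation recovers the simulated alpha peak", {
  for (iaf in c(10, 12.5)) {
    r <- simulate_resting(iaf = iaf, alpha_snr = 6, duration = 60,
                          seed = round(iaf * 10))
    expect_lt(abs(estimate_iaf(r$recording) - iaf), 0.25)
  }
  # pure noise: estimate still lands in band, with a low-prominence warning
  r0 <- simulate_resting(iaf = 10, alpha_snr = -Inf, duration = 60, seed = 1)
  expect_warning(v <- estimate_iaf(r0$recording), "prominence")
  expect_true(v >= 7 && v <= 14)
  rec <- r0$recording
  rec$channels[rec$channels == "O1"] <- "X1"
  rownames(rec$data) <- rec$channels
  expect_error(estimate_iaf(rec), "O1/O2")
})

test_that("epoch averaging is the arithmetic mean across trials", {
  ep <- structure(list(epochs = array(0, c(3, 2, 4)),
                       times = c(-1, 0, 1, 2) * 4, fs = 256,
                       channels = c("A", "B"), dropped = integer(0)),
                  class = "epoch_set")
  base <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4)
  for (tr in 1:3) ep$epochs[tr, , ] <- base
  expect_equal(unname(average_epochs(ep)), base, ignore_attr = TRUE)  # identical trials
  ep$epochs[2, , ] <- -base; ep$epochs[3, , ] <- 0   # +x, -x, 0
  expect_true(all(average_epochs(ep) == 0))
  ep$epochs <- ep$epochs[0, , , drop = FALSE]
  expect_error(average_epochs(ep), "empty")
})

test_that("ITC is 1 for phase-locked trials and matches the null oracle for noise", {
  sch <- build_schedule(50, 1, 2)
  tpl <- make_template(aerp_components("tinnitus"))
  locked <- simulate_session(tpl, sch, itc_level = 1, noise_sd = 0, seed = 1)
  ep <- segment_epochs(locked$recording)
  itc <- compute_itc(ep, iaf = 10)
  expect_true(all(itc >= 0 & itc <= 1))
  expect_true(all(itc > 0.999))
  # random-phase noise trials: mean ITC ~ E|resultant| of 50 unit phasors
  flat <- make_template(aerp_components("tinnitus")[0, ])
  ns <- simulate_session(flat, sch, itc_level = 1, noise_sd = 5, seed = 2)
  itc0 <- compute_itc(segment_epochs(ns$recording), iaf = 10)
  set.seed(3)
  oracle <- mean(replicate(4000, Mod(mean(exp(2i * pi * runif(50))))))
  expect_equal(mean(itc0), oracle, tolerance = 0.20)
  # single trial degenerates to 1 with a warning
  one <- ep; one$epochs <- ep$epochs[1, , , drop = FALSE]
  expect_warning(itc1 <- compute_itc(one, iaf = 10), "single")
  expect_true(all(itc1 == 1))
  expect_error(compute_itc(ep, iaf = 1, halfwidth = 2), "band")
})

test_that("ITC increases with the simulated phase-locking level", {
  sch <- build_schedule(50, 1, 2)
  tpl <- make_template(aerp_components("tinnitus"))
  means <- sapply(c(0, 0.5, 1), function(lev) {
    mean(sapply(1:5, function(s) {
      ss <- simulate_session(tpl, sch, itc_level = lev, noise_sd = 2,
                             seed = 100 + 7 * s)
      mean(compute_itc(segment_epochs(ss$recording), iaf = 10))
    }))
  })
  expect_true(all(diff(means) > 0))
})

test_that("ITC/IAF weighting is multiplicative with the documented factors", {
  avg <- matrix(rnorm(2 * 8), 2, 8, dimnames = list(c("C3", "C4"), NULL))
  attr(avg, "times") <- seq_len(8)
  w1 <- weight_aerp(avg, c(C3 = 1, C4 = 1), iaf = 10)
  expect_equal(w1$waveform, avg, ignore_attr = TRUE)       # identity
  w0 <- weight_aerp(avg, c(C3 = 0, C4 = 1), iaf = 10)
  expect_true(all(w0$waveform["C3", ] == 0))
  wh <- weight_aerp(avg, c(C3 = 0.5, C4 = 0.5), iaf = 10)
  expect_equal(wh$waveform, avg * 0.5, ignore_attr = TRUE) # exact halving
  w8 <- weight_aerp(avg, c(C3 = 1, C4 = 1), iaf = 8)
  expect_equal(w8$waveform, avg * 10 / 8, ignore_attr = TRUE)
  expect_error(weight_aerp(avg, c(C3 = 1.2, C4 = 1)), "0, 1")
})

test_that("grand averaging pools participants and checks compatibility", {
  avg <- matrix(rnorm(2 * 8), 2, 8, dimnames = list(c("C3", "C4"), NULL))
  attr(avg, "times") <- seq_len(8)
  r1 <- weight_aerp(avg, c(C3 = 1, C4 = 1))
  expect_equal(grand_average(list(r1)), r1$waveform, ignore_attr = TRUE)
  r2 <- r1; r2$waveform <- -r1$waveform
  expect_true(all(grand_average(list(r1, r2)) == 0))
  expect_equal(grand_average(list(r1, r1, r1)), r1$waveform,
               ignore_attr = TRUE)
  r3 <- r1; r3$channels <- c("F3", "F4")
  expect_error(grand_average(list(r1, r3)), "incompatible")
})

test_that("AUC of the session difference is a signed trapezoidal integral", {
  times <- seq(-200, 800, length.out = 257)
  mk <- function(m) { rownames(m) <- default_montage(); attr(m, "times") <- times; m }
  z <- mk(matrix(0, 16, 257))
  same <- auc_difference(z, z)
  expect_true(all(same$auc == 0))
  # unit half-sine over 0..1000 ms integrates to 2000/pi uV*ms
  hs <- matrix(0, 16, 257)
  on <- times >= 0 & times <= 800
  hs[8, ] <- ifelse(times >= 0, sin(pi * (times) / 1000), 0)
  a <- auc_difference(mk(hs), z)
  half_sine_int <- function(upper) 1000 / pi * (1 - cos(pi * upper / 1000))
  expect_equal(a$auc[["C4"]], half_sine_int(800), tolerance = 1e-3)
  # a full 0-1000 ms half-sine window equals the analytic 2000/pi
  times2 <- seq(0, 1000, length.out = 1001)
  mk2 <- function(m) { rownames(m) <- default_montage(); attr(m, "times") <- times2; m }
  hs2 <- matrix(0, 16, 1001); hs2[8, ] <- sin(pi * times2 / 1000)
  a2 <- auc_difference(mk2(hs2), mk2(matrix(0, 16, 1001)))
  expect_equal(a2$auc[["C4"]], 2000 / pi, tolerance = 1e-3)
  expect_equal(a2$auc_ch, "C4")
  expect_equal(a2$auc_max, a2$auc[["C4"]])
})

test_that("AUC difference is antisymmetric in its arguments", {
  set.seed(5)
  times <- seq(-200, 800, length.out = 257)
  mk <- function() {
    m <- matrix(rnorm(16 * 257), 16, 257)
    rownames(m) <- default_montage(); attr(m, "times") <- times; m
  }
  for (i in 1:5) {
    x <- mk(); y <- mk()
    expect_equal(auc_difference(x, y)$auc, -auc_difference(y, x)$auc)
  }
})

test_that("component peaks match the template parameter sets", {
  tin <- make_template(aerp_components("tinnitus"), fs = 256)
  pk <- detect_components(tin$wave, list(N1 = c(100, 200), P3 = c(300, 460)),
                          times = tin$times)
  expect_equal(pk$amplitude[pk$component == "N1"], -1.7, tolerance = 0.05)
  expect_equal(pk$latency[pk$component == "N1"], 150, tolerance = 1000 / 256)
  expect_equal(pk$latency[pk$component == "P3"], 380, tolerance = 1000 / 256)
  ctl <- make_template(aerp_components("control"), fs = 256)
  pc <- detect_components(ctl$wave, list(P2 = c(150, 260), P3 = c(280, 420)),
                          times = ctl$times)
  expect_equal(pc$amplitude[pc$component == "P2"], 2.9, tolerance = 0.05)
  expect_equal(pc$latency[pc$component == "P3"], 340, tolerance = 1000 / 256)
  # zero waveform: amplitude 0 at the window start (earliest tie-break)
  z <- detect_components(numeric(256), list(N1 = c(100, 200)),
                         times = tin$times)
  expect_equal(z$amplitude, 0)
  expect_equal(z$latency, min(tin$times[tin$times >= 100]))
  expect_error(detect_components(tin$wave, list(X = c(700, 900)),
                                 times = tin$times), "window")
})
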