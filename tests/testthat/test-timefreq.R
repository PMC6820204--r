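# Morlet wavelet power, dB baselining, band/window extraction and the
# offset-locked analysis.

test_that("a stationary sinusoid produces a flat ridge at its frequency", {
  ep <- tone_epochs(10, n_trials = 3)
  tf <- morlet_power(ep, wavelet_config())
  ridge_f <- tf$freqs[which.max(apply(tf$power[1, , ], 1, mean))]
  expect_equal(ridge_f, 10)
  ridge <- tf$power[1, tf$freqs == 10, ]
  expect_lt((max(ridge) - min(ridge)) / mean(ridge), 0.01)
})

test_that("wavelet grid covers -0.6 to 1.2 s in 10 ms steps with t = 0 on grid", {
  ep <- tone_epochs(8, n_trials = 2)
  tf <- morlet_power(ep, wavelet_config(), freq_range = c(7, 10))
  expect_equal(length(tf$times), 181)
  expect_true(any(tf$times == 0))
  expect_equal(diff(tf$times)[1], 0.010)
  expect_equal(length(tf$freqs), 16)       # 7.0 ... 10.0 in 0.2 Hz steps
})

test_that("a x2 amplitude step yields an asymptotic power ratio of 4", {
  fs <- 1000
  n <- 7800
  tt <- seq(-1.5, by = 1 / fs, length.out = n)
  x <- cos(2 * pi * 12 * tt) * ifelse(tt < 0, 1, 2)
  ep <- epoched_recording(array(rep(x, each = 2), c(2, 1, n)), fs, tt)
  tf <- morlet_power(ep, wavelet_config(), freq_range = c(10, 14))
  pre <- mean(tf$power[1, tf$freqs == 12, tf$times <= -0.4])
  post <- mean(tf$power[1, tf$freqs == 12, tf$times >= 0.6])
  expect_equal(post / pre, 4, tolerance = 0.02)
})

test_that("all-zero input gives all-zero power", {
  fs <- 1000
  n <- 7800
  ep <- epoched_recording(array(0, c(2, 1, n)), fs,
                          seq(-1.5, by = 1 / fs, length.out = n))
  tf <- morlet_power(ep, wavelet_config(), freq_range = c(5, 6))
  expect_equal(max(tf$power), 0)
})

test_that("white-noise wavelet power is flat across frequency", {
  set.seed(21)
  ep <- noise_epochs(30, t_range = c(-1.5, 6.3))
  tf <- morlet_power(ep, wavelet_config())
  prof_low <- apply(tf$power[1, tf$freqs <= 30, ], 1, mean)
  prof_high <- apply(tf$power[1, tf$freqs >= 40, ], 1, mean)
  # unit-energy wavelets: expected |coef|^2 equals the noise variance at
  # every frequency (within Monte-Carlo error)
  expect_lt(sd(prof_low) / mean(prof_low), 0.15)
  expect_lt(sd(prof_high) / mean(prof_high), 0.15)
  expect_equal(mean(prof_high) / mean(prof_low), 1, tolerance = 0.1)
})

test_that("wavelet temporal resolution follows cycles over frequency", {
  fs <- 1000
  n <- 7800
  tt <- seq(-1.5, by = 1 / fs, length.out = n)
  x <- numeric(n); x[which.min(abs(tt))] <- 1       # impulse at t = 0
  ep <- epoched_recording(array(x, c(1, 1, n)), fs, tt)
  cfg <- wavelet_config()
  sigma_for <- function(f) {
    tf <- morlet_power(ep, cfg, freq_range = c(f, f))
    p <- drop(tf$power[1, 1, ])
    sel <- p > max(p) * 1e-4
    co <- coef(lm(log(p[sel]) ~ I(tf$times[sel]^2)))
    sqrt(-1 / (2 * unname(co[2])))   # SD of the Gaussian power envelope
  }
  cyc <- function(f) 3 + 9 * (f - 2) / 28
  expected_ratio <- (cyc(5) / 5) / (cyc(20) / 20)
  expect_equal(sigma_for(5) / sigma_for(20), expected_ratio,
               tolerance = 0.05)
})

test_that("an analysis window too close to the epoch edge names the frequency", {
  fs <- 1000
  n <- 1900
  ep <- epoched_recording(array(rnorm(2 * n), c(2, 1, n)), fs,
                          seq(-0.7, by = 1 / fs, length.out = n))
  expect_error(morlet_power(ep, wavelet_config(), freq_range = c(2, 5)), "2 Hz")
})

test_that("dB baselining has the textbook fixed points and exact inverse", {
  ep <- tone_epochs(10, n_trials = 2)
  tf <- morlet_power(ep, wavelet_config(), freq_range = c(8, 12))
  db <- baseline_db(tf)
  # stationary signal: P equals its baseline mean -> 0 dB everywhere
  expect_lt(max(abs(db$power[1, db$freqs == 10, ])), 0.05)
  expect_identical(db$units, "dB")
  expect_error(baseline_db(db), "twice")
  back <- undo_baseline_db(db)
  expect_equal(back$power, tf$power, tolerance = 1e-12)
  # +10 dB for a tenfold power increase
  tf2 <- tf
  tf2$power[, , tf$times > 0] <- tf$power[, , tf$times > 0] * 10
  db2 <- baseline_db(tf2)
  expect_equal(mean(db2$power[1, 1, tf$times > 0.1]), 10, tolerance = 0.2)
})

test_that("halving an oscillation's amplitude reads as about -6 dB", {
  fs <- 1000
  n <- 7800
  tt <- seq(-1.5, by = 1 / fs, length.out = n)
  x <- cos(2 * pi * 8 * tt) * ifelse(tt < 0.1, 1, 0.5)
  ep <- epoched_recording(array(rep(x, each = 2), c(2, 1, n)), fs, tt)
  tf <- morlet_power(ep, wavelet_config(), freq_range = c(7, 10))
  db <- baseline_db(tf)
  alpha <- band_window_power(db, c(7, 10), c(0.5, 1.2))
  expect_lt(abs(unname(alpha) - 20 * log10(0.5)), 0.1)
})

test_that("band and window selection uses inclusive grid endpoints", {
  ep <- tone_epochs(8, n_trials = 2)
  tf <- morlet_power(ep, wavelet_config(), freq_range = c(2, 30))
  expect_equal(sum(tf$freqs >= 7 - 1e-9 & tf$freqs <= 10 + 1e-9), 16)
  sel_t <- tf$times[tf$times >= 0.5 - 1e-9 & tf$times <= 1.2 + 1e-9]
  expect_equal(length(sel_t), 71)
  expect_error(band_window_power(tf, c(300, 400), c(0.5, 1.2)), "empty")
})

test_that("offset-locked power is near zero without suppression", {
  p <- small_params(suppression_clear = 0, suppression_vocoded = 0,
                    hg_response_amp = 0)
  rec <- simulate_hemisphere(p, make_contact_set(p)[1:9, ], 31)
  off <- offset_locked_power(rec$sentence)
  expect_lt(max(abs(off)), 1.0)
})

test_that("offset-locked analysis needs durations and long-enough sentences", {
  ep <- tone_epochs(8, n_trials = 3)
  expect_error(offset_locked_power(ep), "durations")
  ep$durations <- rep(0.8, 3)
  expect_error(offset_locked_power(ep), "at least")
})
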