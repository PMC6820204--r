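# Conditioning: interpolating line-noise notch, Fourier resampling,
# epoching conventions.

test_that("a pure 60 Hz tone is removed almost entirely", {
  fs <- 1000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  rec <- lfp_recording(sin(2 * pi * 60 * tt), fs)
  out <- remove_line_noise(rec)
  p_in <- mean(rec$data^2)
  p_out <- mean(out$data^2)
  expect_lt(p_out / p_in, 0.01)
})

test_that("notch leaves broadband 1/f band power essentially untouched", {
  fs <- 1000
  x <- spectral_background(1, 10000, fs, seed = 4)
  rec <- lfp_recording(x, fs)
  out <- remove_line_noise(rec)
  band_power <- function(y) {
    X <- Mod(fft(y))^2
    f <- abs(hgalpha:::fft_freqs(length(y), fs))
    sum(X[f >= 2 & f <= 30])
  }
  expect_equal(band_power(drop(out$data)) / band_power(x), 1,
               tolerance = 0.05)
})

test_that("DC input passes the notch unchanged", {
  rec <- lfp_recording(rep(2.5, 1000), 1000)
  out <- remove_line_noise(rec)
  expect_equal(drop(out$data), rep(2.5, 1000), tolerance = 1e-10)
})

test_that("notch attenuates every configured harmonic", {
  fs <- 1000
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 60 * tt) + 0.5 * sin(2 * pi * 120 * tt) +
    0.25 * sin(2 * pi * 180 * tt) + sin(2 * pi * 10 * tt)
  out <- remove_line_noise(lfp_recording(x, fs))
  X <- Mod(fft(drop(out$data)))^2
  f <- abs(hgalpha:::fft_freqs(length(x), fs))
  Xin <- Mod(fft(x))^2
  for (h in c(60, 120, 180)) {
    sel <- abs(f - h) <= 1
    expect_lt(sum(X[sel]) / sum(Xin[sel]), 0.01)   # >= 20 dB down
  }
  sel10 <- abs(f - 10) <= 1                         # passband untouched
  expect_equal(sum(X[sel10]) / sum(Xin[sel10]), 1, tolerance = 0.01)
})

test_that("downsampling 2000 to 1000 Hz halves the sample count", {
  rec <- lfp_recording(rnorm(4000), 2000)
  out <- resample_recording(rec, 1000)
  expect_equal(ncol(out$data), 2000)
  expect_equal(out$fs, 1000)
  expect_error(resample_recording(out, 2000), "exceed")
})

test_that("the 2034.5 Hz acquisition rate resamples to 1000 Hz", {
  fs <- 2034.5
  n <- round(10 * fs)
  tt <- (0:(n - 1)) / fs
  rec <- lfp_recording(sin(2 * pi * 10 * tt), fs)
  out <- resample_recording(rec, 1000)
  expect_equal(ncol(out$data), round(n * 1000 / fs))
  # amplitude-fit oracle on the central region
  y <- drop(out$data)
  ty <- (seq_along(y) - 1) / 1000
  mid <- seq(1000, length(y) - 1000)
  co <- coef(lm(y[mid] ~ sin(2 * pi * 10 * ty[mid]) +
                  cos(2 * pi * 10 * ty[mid]) - 1))
  expect_equal(sqrt(sum(co^2)), 1, tolerance = 0.01)
})

test_that("resampling is linear", {
  x <- rnorm(3000)
  rec1 <- lfp_recording(x, 2000)
  rec2 <- lfp_recording(3.7 * x, 2000)
  a <- resample_recording(rec1, 1000)
  b <- resample_recording(rec2, 1000)
  expect_equal(b$data, 3.7 * a$data, tolerance = 1e-12)
})

test_that("epoching follows the half-open sample-grid convention", {
  fs <- 1000
  rec <- lfp_recording(matrix(rnorm(2 * 20000), 2), fs)
  ep <- epoch_recording(rec, onsets = c(3, 9), window = c(-1.5, 6.3))
  expect_equal(dim(ep$data), c(2, 2, 7800))
  expect_equal(ep$times[1], -1.5)
  expect_equal(which(abs(ep$times) < 1e-9), 1501)   # onset sample at t = 0
  # epoch content equals the raw slice exactly (no filtering inside epoching)
  idx <- (3 - 1.5) * fs + 1:7800
  expect_identical(ep$data[1, 1, ], rec$data[1, idx])
})

test_that("adjacent epochs tile the recording without overlap", {
  fs <- 100
  x <- seq_len(1000)
  rec <- lfp_recording(x, fs)
  ep <- epoch_recording(rec, onsets = c(1, 2, 3), window = c(0, 1))
  glued <- c(t(ep$data[, 1, ]))
  expect_equal(glued, x[101:400])
})

test_that("out-of-bounds onsets are rejected per trial with a warning", {
  rec <- lfp_recording(rnorm(5000), 1000)
  expect_warning(ep <- epoch_recording(rec, onsets = c(0.2, 2, 4.9),
                                       window = c(-0.5, 0.5)),
                 "rejected")
  expect_equal(dim(ep$data)[1], 1)
  ep0 <- epoch_recording(rec, onsets = numeric(0), window = c(-0.5, 0.5))
  expect_equal(dim(ep0$data)[1], 0)
})

test_that("fused preprocessing equals notch followed by resampling", {
  p <- small_params(n_trials_per_condition = 2, sample_rate = 2000)
  rec <- simulate_hemisphere(p, make_contact_set(p)[1:9, ], 3)$sentence
  cfg <- preprocess_config()
  fused <- preprocess_epochs(rec, cfg)
  seq2 <- resample_recording(remove_line_noise(rec, cfg), cfg$target_rate)
  expect_equal(fused$data, seq2$data, tolerance = 1e-9)
  expect_equal(fused$fs, 1000)
  expect_equal(dim(fused$data)[3], dim(rec$data)[3] / 2)
})
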