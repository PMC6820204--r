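# Stimulus synthesis: click trains, the three-band noise vocoder, sentence
# surrogates, RMS normalization and WAV round-trips.

test_that("click trains contain exactly rate x duration impulses at all rates", {
  for (rate in c(25, 50, 100, 125, 150, 200)) {
    ct <- generate_click_train(click_train_spec(rate), seed = 1)
    expect_equal(sum(ct$samples != 0), rate * 0.160)
    expect_true(all(ct$samples %in% c(0, 1)))
    expect_equal(ct$duration, 0.160)
  }
})

test_that("click-train onset schedule is seeded and normally distributed", {
  a <- generate_click_train(click_train_spec(100), seed = 7)
  b <- generate_click_train(click_train_spec(100), seed = 7)
  c <- generate_click_train(click_train_spec(100), seed = 8)
  expect_identical(attr(a, "schedule"), attr(b, "schedule"))
  expect_false(identical(attr(a, "schedule"), attr(c, "schedule")))
  iv <- diff(attr(a, "schedule")$onset_s)
  expect_equal(mean(iv), 2.0, tolerance = 0.01)
  expect_lt(sd(iv), 0.05)
})

test_that("unsupported click rates are rejected", {
  expect_error(click_train_spec(60), "unsupported click rate")
  expect_error(click_train_spec(100, sample_rate = 150), "twice the click rate")
})

test_that("vocoding a 1 kHz tone puts its energy into the middle band", {
  fs <- 16000
  tt <- seq(0, 1, by = 1 / fs)
  tone <- audio_stimulus(sin(2 * pi * 1000 * tt), fs, "clear")
  v <- vocode(tone, vocoder_spec(sample_rate = fs), seed = 3)
  frac_mid <- band_energy_fraction(v$samples, fs, c(558, 2264))
  expect_gt(frac_mid, 0.90)
  # long-term spectrum essentially confined to the full vocoder range
  frac_out <- 1 - band_energy_fraction(v$samples, fs, c(45, 8000))
  expect_lt(frac_out, 0.01)
  # output level matches the input RMS
  expect_equal(stimulus_rms(v), stimulus_rms(tone), tolerance = 1e-9)
})

test_that("vocoder band reconstruction has bounded cross-band leakage", {
  fs <- 44100
  s <- make_sentence_surrogate(1.5, seed = 4, sample_rate = fs)
  spec <- vocoder_spec(sample_rate = fs)
  edges <- spec$band_edges
  core <- function(b) c(edges[b] * 1.15, edges[b + 1] * 0.85)
  for (b in 1:3) {
    # vocode a band-limited input; its energy must stay out of the cores
    # of the other two bands (leakage < 5% of the in-band energy)
    x <- hgalpha:::fir_hann_bandpass(s$samples, edges[b], edges[b + 1], fs,
                                     spec$band_filter_window_len)
    vb <- vocode(audio_stimulus(x, fs, "clear"), spec, seed = 6)
    own <- band_energy_fraction(vb$samples, fs, core(b))
    leak <- sum(vapply(setdiff(1:3, b), function(j) {
      band_energy_fraction(vb$samples, fs, core(j))
    }, numeric(1)))
    expect_lt(leak, 0.05 * own)
  }
})

test_that("all-zero input vocodes to all-zero output", {
  fs <- 16000
  z <- audio_stimulus(numeric(fs), fs, "clear")
  expect_equal(max(abs(vocode(z)$samples)), 0)
})

test_that("vocode validates its input", {
  fs <- 16000
  tone <- audio_stimulus(sin(2 * pi * 100 * (1:fs) / fs), fs, "vocoded")
  expect_error(vocode(tone), "clear")
  expect_error(vocoder_spec(sample_rate = 8000), "too low")
  expect_error(vocoder_spec(band_edges = c(50, 40, 2264, 8000)), "increasing")
})

test_that("sentence surrogates keep duration bookkeeping and are seeded", {
  fs <- 16000
  s <- make_sentence_surrogate(1.223, seed = 1, sample_rate = fs)
  expect_equal(length(s$samples), round(1.223 * fs))
  expect_identical(s$samples,
                   make_sentence_surrogate(1.223, seed = 1, sample_rate = fs)$samples)
  expect_error(make_sentence_surrogate(0.5), "outside range")
  expect_error(make_sentence_surrogate(5.0), "outside range")
})

test_that("sentence surrogate envelope modulation peaks in the 2-8 Hz range", {
  fs <- 16000
  s <- make_sentence_surrogate(4.0, seed = 2, sample_rate = fs)
  # crude Hilbert-style envelope: magnitude of the analytic signal
  n <- length(s$samples)
  X <- fft(s$samples)
  h <- c(1, rep(2, floor((n - 1) / 2)), rep(0, n - 1 - floor((n - 1) / 2)))
  env <- Mod(fft(X * h, inverse = TRUE) / n)
  env <- env - mean(env)
  E <- Mod(fft(env))^2
  f <- abs(hgalpha:::fft_freqs(n, fs))
  in_band <- sum(E[f >= 2 & f <= 8])
  out_band <- sum(E[f > 8 & f <= 30])
  expect_gt(in_band, out_band)
})

test_that("RMS normalization equalizes a stimulus set to 1e-6 relative", {
  fs <- 16000
  set <- list(make_sentence_surrogate(1.3, 1, fs),
              make_sentence_surrogate(2.0, 2, fs),
              audio_stimulus(0.3 * sin(2 * pi * 440 * (1:fs) / fs), fs, "clear"))
  out <- normalize_rms(set)
  rms <- vapply(out, stimulus_rms, numeric(1))
  expect_lt(diff(range(rms)) / mean(rms), 1e-6)
})

test_that("WAV files round-trip in both encodings", {
  fs <- 8000
  x <- 0.5 * sin(2 * pi * 440 * (0:(fs - 1)) / fs)
  for (bits in c(16, 32)) {
    path <- tempfile(fileext = ".wav")
    write_wav(x, path, fs, bit_depth = bits)
    back <- read_wav(path)
    expect_equal(back$sample_rate, fs)
    tol <- if (bits == 16) 1e-4 else 1e-7
    expect_equal(drop(back$samples), x, tolerance = tol)
    unlink(path)
  }
})

test_that("stimulus schedules export to CSV", {
  ct <- generate_click_train(click_train_spec(100, n_trials = 5), seed = 1)
  path <- tempfile(fileext = ".csv")
  sched <- export_stimulus_schedule(list(ct), path)
  expect_true(file.exists(path))
  expect_equal(nrow(sched), 5)
  expect_equal(sched$condition, rep("click", 5))
  unlink(path)
})
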