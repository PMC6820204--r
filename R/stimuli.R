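# Acoustic stimulus synthesis: click trains for functional localization and
# clear / three-band noise-vocoded sentence-like signals for the main
# experiment.

CLICK_RATES <- c(25, 50, 100, 125, 150, 200)
SENTENCE_DURATION_RANGE <- c(1.223, 4.703)

#' Click-train stimulus specification
#'
#' Click trains are 160 ms long and presented at one of six repetition rates;
#' successive train onsets are separated by intervals drawn from a normal
#' distribution (mean 2 s, SD 10 ms).
#'
#' @param rate click repetition rate in Hz; one of 25, 50, 100, 125, 150, 200.
#' @param duration train duration in seconds.
#' @param n_trials number of train presentations.
#' @param onset_interval_mean,onset_interval_sd onset-to-onset interval
#'   distribution in seconds.
#' @param sample_rate audio sampling rate in Hz.
#' @return A `click_train_spec` list.
#' @export
click_train_spec <- function(rate, duration = 0.160, n_trials = 50,
                             onset_interval_mean = 2.0,
                             onset_interval_sd = 0.010,
                             sample_rate = 44100) {
  if (!rate %in% CLICK_RATES) {
    stop_invalid("unsupported click rate ", rate, "; must be one of ",
                 paste(CLICK_RATES, collapse = ", "))
  }
  if (duration <= 0 || n_trials <= 0 || onset_interval_mean <= 0 ||
      onset_interval_sd < 0 || sample_rate <= 0) {
    stop_invalid("click-train spec values must be positive")
  }
  if (sample_rate < 2 * rate) {
    stop_invalid("sample_rate must be at least twice the click rate")
  }
  structure(list(rate = rate, duration = duration, n_trials = n_trials,
                 onset_interval_mean = onset_interval_mean,
                 onset_interval_sd = onset_interval_sd,
                 sample_rate = sample_rate),
            class = "click_train_spec")
}

#' Three-band noise-vocoder specification
#'
#' The vocoder splits the signal into three contiguous bands (50-558,
#' 558-2264, 2264-8000 Hz), extracts each band's amplitude envelope by
#' full-wave rectification and 30 Hz fourth-order Butterworth low-pass
#' filtering, and reimposes the envelopes on band-limited noise. Band filters
#' are FIR Hann bandpass filters with an 801-sample window at 44.1 kHz; for
#' other rates the window length is scaled proportionally (rounded to odd) to
#' preserve transition bandwidth.
#'
#' @param band_edges ordered band edges in Hz.
#' @param envelope_cutoff envelope low-pass cutoff in Hz.
#' @param envelope_filter_order Butterworth order for envelope smoothing.
#' @param band_filter_window_len FIR window length in samples at
#'   `reference_rate`.
#' @param sample_rate audio sampling rate in Hz.
#' @param reference_rate rate at which `band_filter_window_len` is defined.
#' @return A `vocoder_spec` list.
#' @export
vocoder_spec <- function(band_edges = c(50, 558, 2264, 8000),
                         envelope_cutoff = 30, envelope_filter_order = 4,
                         band_filter_window_len = 801, sample_rate = 44100,
                         reference_rate = 44100) {
  if (any(diff(band_edges) <= 0)) {
    stop_invalid("band edges must be strictly increasing")
  }
  if (sample_rate < 2 * max(band_edges)) {
    stop_invalid("sample rate ", sample_rate,
                 " too low for top band edge ", max(band_edges), " Hz")
  }
  if (envelope_cutoff >= sample_rate / 2) {
    stop_invalid("envelope cutoff must be below Nyquist")
  }
  win_len <- round(band_filter_window_len * sample_rate / reference_rate)
  if (win_len %% 2 == 0) win_len <- win_len + 1
  structure(list(band_edges = band_edges, envelope_cutoff = envelope_cutoff,
                 envelope_filter_order = envelope_filter_order,
                 band_filter_window_len = win_len, sample_rate = sample_rate),
            class = "vocoder_spec")
}

#' Audio stimulus container
#'
#' @param samples pressure waveform (arbitrary units).
#' @param sample_rate sampling rate in Hz.
#' @param condition one of `"clear"`, `"vocoded"`, `"click"`.
#' @return An `audio_stimulus` list; `duration` is derived from the sample
#'   count.
#' @export
audio_stimulus <- function(samples, sample_rate,
                           condition = c("clear", "vocoded", "click")) {
  condition <- match.arg(condition)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 condition = condition,
                 duration = length(samples) / sample_rate),
            class = "audio_stimulus")
}

#' @export
print.audio_stimulus <- function(x, ...) {
  cat(sprintf("<audio_stimulus: %s> %.3f s @ %g Hz, RMS %.4g\n",
              x$condition, x$duration, x$sample_rate, stimulus_rms(x)))
  invisible(x)
}

#' Root-mean-square level of a stimulus
#' @param stimulus an [audio_stimulus()].
#' @return RMS of the waveform.
#' @export
stimulus_rms <- function(stimulus) sqrt(mean(stimulus$samples^2))

#' Generate a click train
#'
#' Produces a train of single-sample unit impulses at `spec$rate` spanning
#' exactly `spec$duration` seconds, together with a reproducible trial onset
#' schedule (attribute `"schedule"`): `spec$n_trials` onsets whose successive
#' intervals are drawn from N(onset_interval_mean, onset_interval_sd).
#'
#' @param spec a [click_train_spec()].
#' @param seed integer seed for the onset schedule.
#' @return An [audio_stimulus()] with condition `"click"` and a `"schedule"`
#'   attribute (data.frame: trial, onset_s).
#' @export
generate_click_train <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "click_train_spec"))
  fs <- spec$sample_rate
  n_samples <- round(spec$duration * fs)
  n_clicks <- round(spec$rate * spec$duration)
  click_idx <- round((seq_len(n_clicks) - 1) / spec$rate * fs) + 1
  x <- numeric(n_samples)
  x[click_idx] <- 1
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  intervals <- rnorm(spec$n_trials, spec$onset_interval_mean,
                     spec$onset_interval_sd)
  onsets <- cumsum(c(0.5, intervals[-spec$n_trials]))
  out <- audio_stimulus(x, fs, "click")
  attr(out, "schedule") <- data.frame(trial = seq_len(spec$n_trials),
                                      onset_s = onsets)
  out
}

# FIR Hann bandpass applied with zero phase (group-delay compensated).
fir_hann_bandpass <- function(x, lo, hi, fs, n_taps) {
  ny <- fs / 2
  b <- signal::fir1(n_taps - 1, c(lo, hi) / ny, type = "pass",
                    window = signal::hanning(n_taps))
  y <- signal::fftfilt(b, c(x, numeric(n_taps)))
  delay <- (n_taps - 1) / 2
  y[seq_along(x) + delay]
}

#' Three-band noise vocoding
#'
#' Filters the input into the spec's three bands, extracts each band's
#' envelope (full-wave rectification, 30 Hz 4th-order Butterworth low-pass),
#' applies the envelopes to band-limited noise in the same bands, sums the
#' bands, and rescales the result to the input RMS.
#'
#' @param stimulus a clear [audio_stimulus()].
#' @param spec a [vocoder_spec()]; its sample rate must match the stimulus.
#' @param seed integer seed for the noise carriers.
#' @return An [audio_stimulus()] with condition `"vocoded"`.
#' @export
vocode <- function(stimulus, spec = vocoder_spec(sample_rate = stimulus$sample_rate),
                   seed = 1) {
  stopifnot(inherits(stimulus, "audio_stimulus"), inherits(spec, "vocoder_spec"))
  if (stimulus$condition != "clear") {
    stop_invalid("vocode expects a clear stimulus")
  }
  if (spec$sample_rate != stimulus$sample_rate) {
    stop_invalid("vocoder/stimulus sample-rate mismatch")
  }
  fs <- spec$sample_rate
  x <- stimulus$samples
  n <- length(x)
  bf <- signal::butter(spec$envelope_filter_order,
                       spec$envelope_cutoff / (fs / 2), type = "low")
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  out <- numeric(n)
  for (b in seq_len(length(spec$band_edges) - 1)) {
    lo <- spec$band_edges[b]
    hi <- spec$band_edges[b + 1]
    band <- fir_hann_bandpass(x, lo, hi, fs, spec$band_filter_window_len)
    env <- signal::filtfilt(bf, abs(band))
    env <- pmax(env, 0)
    carrier <- fir_hann_bandpass(rnorm(n), lo, hi, fs,
                                 spec$band_filter_window_len)
    out <- out + env * carrier
  }
  in_rms <- stimulus_rms(stimulus)
  out_rms <- sqrt(mean(out^2))
  if (in_rms > 0 && out_rms > 0) out <- out * (in_rms / out_rms)
  audio_stimulus(out, fs, "vocoded")
}

#' Speech-shaped modulated-noise sentence surrogate
#'
#' Stands in for recorded sentences: broadband noise with a speech-like
#' spectral tilt (flat to 500 Hz, -9 dB/octave above) and a positive
#' low-frequency (2-8 Hz) envelope modulation, mimicking the syllabic
#' rhythm of connected speech. Deterministic given `seed`.
#'
#' @param duration duration in seconds; must lie in the sentence range
#'   \[1.223, 4.703\] s.
#' @param seed integer seed.
#' @param sample_rate sampling rate in Hz.
#' @param modulation_depth envelope modulation depth (0-1 scale).
#' @return A clear [audio_stimulus()].
#' @export
make_sentence_surrogate <- function(duration, seed = 1, sample_rate = 44100,
                                    modulation_depth = 0.8) {
  if (duration < SENTENCE_DURATION_RANGE[1] - .grid_eps ||
      duration > SENTENCE_DURATION_RANGE[2] + .grid_eps) {
    stop_invalid("sentence duration ", duration, " outside range [",
                 SENTENCE_DURATION_RANGE[1], ", ", SENTENCE_DURATION_RANGE[2],
                 "] s")
  }
  n <- round(duration * sample_rate)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed)
  # spectrally shaped carrier
  freqs <- fft_freqs(n, sample_rate)
  af <- abs(freqs)
  shape <- ifelse(af <= 500, 1, (pmax(af, 500) / 500)^(-1.5))
  shape[af < 50 | af > 8000] <- 0
  spec <- fft(rnorm(n)) * shape
  carrier <- Re(fft(spec, inverse = TRUE)) / n
  # 2-8 Hz positive envelope
  mshape <- as.numeric(af >= 2 & af <= 8)
  mod <- Re(fft(fft(rnorm(n)) * mshape, inverse = TRUE)) / n
  mod <- mod / stats::sd(mod)
  env <- pmax(1 + modulation_depth * mod, 0)
  audio_stimulus(carrier * env, sample_rate, "clear")
}

#' Normalize a stimulus set for RMS intensity
#'
#' Scales every stimulus in the set to the same root-mean-square level.
#'
#' @param stimuli list of [audio_stimulus()] objects.
#' @param target_rms RMS to scale to; defaults to the set's median RMS.
#' @return List of stimuli with equal RMS.
#' @export
normalize_rms <- function(stimuli, target_rms = NULL) {
  rms <- vapply(stimuli, stimulus_rms, numeric(1))
  if (any(rms == 0)) stop_invalid("cannot RMS-normalize an all-zero stimulus")
  if (is.null(target_rms)) target_rms <- median(rms)
  lapply(seq_along(stimuli), function(i) {
    s <- stimuli[[i]]
    s$samples <- s$samples * (target_rms / rms[i])
    s
  })
}

#' Export a stimulus presentation schedule as CSV
#'
#' @param stimuli list of stimuli (each contributes one row per trial of its
#'   `"schedule"` attribute, or one row if it has none).
#' @param path output CSV path.
#' @return The schedule data.frame, invisibly.
#' @export
export_stimulus_schedule <- function(stimuli, path) {
  rows <- lapply(seq_along(stimuli), function(i) {
    s <- stimuli[[i]]
    sched <- attr(s, "schedule")
    if (is.null(sched)) sched <- data.frame(trial = 1L, onset_s = 0)
    data.frame(stimulus = i, trial = sched$trial, condition = s$condition,
               onset_s = sched$onset_s, duration_s = s$duration)
  })
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}

# frequency of each DFT bin (two-sided, Hz)
fft_freqs <- function(n, fs) {
  k <- seq_len(n) - 1
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

# save/restore global RNG state so seeded helpers do not disturb the caller
save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
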