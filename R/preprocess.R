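# Conditioning of raw multi-channel recordings: line-noise removal by
# spectrum interpolation, Fourier-domain rational resampling to the analysis
# rate, and epoching around stimulus onsets.

#' Preprocessing configuration
#'
#' @param line_freq power-line fundamental, Hz.
#' @param n_harmonics number of harmonics (including the fundamental) to
#'   remove.
#' @param notch_halfwidth half-width of the interpolated notch, Hz.
#' @param target_rate analysis sampling rate, Hz.
#' @param epoch_window epoch limits relative to stimulus onset, s.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(line_freq = 60, n_harmonics = 3,
                              notch_halfwidth = 1, target_rate = 1000,
                              epoch_window = c(-1.5, 6.3)) {
  stopifnot(line_freq > 0, n_harmonics >= 0, target_rate > 0,
            epoch_window[1] < epoch_window[2])
  if (epoch_window[1] > -0.6 || epoch_window[2] < 1.2) {
    stop_invalid("epoch window must contain the analysis window [-0.6, 1.2] s")
  }
  structure(list(line_freq = line_freq, n_harmonics = n_harmonics,
                 notch_halfwidth = notch_halfwidth,
                 target_rate = target_rate, epoch_window = epoch_window),
            class = "preprocess_config")
}

# Interpolating notch on a samples x traces matrix: replaces the magnitude
# of DFT bins within +/- halfwidth of each harmonic with the mean magnitude
# of the flanking bands (1-3 Hz away), keeping the original phase and
# Hermitian symmetry. DC and untouched bins pass through exactly.
notch_matrix <- function(M, fs, line_freq, n_harmonics, halfwidth) {
  n <- nrow(M)
  X <- notch_bins(mvfft(M), fs, line_freq, n_harmonics, halfwidth)
  Re(mvfft(X, inverse = TRUE)) / n
}

# the bin-replacement core, on an already-transformed samples x traces
# spectrum
notch_bins <- function(X, fs, line_freq, n_harmonics, halfwidth) {
  n <- nrow(X)
  af <- abs(fft_freqs(n, fs))
  for (h in seq_len(n_harmonics)) {
    f0 <- h * line_freq
    if (f0 >= fs / 2) break
    target <- which(af >= f0 - halfwidth & af <= f0 + halfwidth)
    flank <- which((af > f0 + halfwidth & af <= f0 + 3 * halfwidth + 2) |
                     (af < f0 - halfwidth & af >= f0 - 3 * halfwidth - 2))
    if (!length(target) || !length(flank)) next
    ref_mag <- matrix(colMeans(Mod(X[flank, , drop = FALSE])),
                      length(target), ncol(X), byrow = TRUE)
    mag <- Mod(X[target, , drop = FALSE])
    scale <- ifelse(mag > 0, ref_mag / mag, 0)
    X[target, ] <- X[target, , drop = FALSE] * scale
  }
  X
}

# spectrum truncation on an already-transformed matrix
truncate_spectrum <- function(X, n_out) {
  n <- nrow(X)
  Sd <- matrix(0i, n_out, ncol(X))
  nh <- min(floor((n_out - 1) / 2), floor((n - 1) / 2))
  Sd[1, ] <- X[1, ]
  if (nh > 0) {
    Sd[2:(nh + 1), ] <- X[2:(nh + 1), , drop = FALSE]
    Sd[n_out - (1:nh) + 1, ] <- X[n - (1:nh) + 1, , drop = FALSE]
  }
  Sd
}

#' Line-noise removal and resampling in one pass
#'
#' Equivalent to [remove_line_noise()] followed by [resample_recording()]
#' (both operate bin-wise in the frequency domain, so the order is
#' immaterial), but shares one transform per trace. Used by the pipeline on
#' epoched simulated data.
#'
#' @param epochs an [epoched_recording()].
#' @param config a [preprocess_config()].
#' @return The conditioned [epoched_recording()] at `config$target_rate`.
#' @export
preprocess_epochs <- function(epochs, config = preprocess_config()) {
  stopifnot(inherits(epochs, "epoched_recording"))
  if (config$target_rate > epochs$fs) {
    stop_invalid("target_rate must not exceed the current sampling rate")
  }
  n <- dim(epochs$data)[3]
  n_out <- round(n * config$target_rate / epochs$fs)
  res <- apply_trace_matrix(epochs, function(M, fs) {
    X <- notch_bins(mvfft(M), fs, config$line_freq, config$n_harmonics,
                    config$notch_halfwidth)
    Re(mvfft(truncate_spectrum(X, n_out), inverse = TRUE)) * (n_out / n) / n_out
  })
  times <- seq(epochs$times[1], by = 1 / config$target_rate,
               length.out = n_out)
  epoched_recording(res$data, config$target_rate, times, epochs$conditions,
                    epochs$durations, epochs$contact_ids)
}

#' Remove power-line noise
#'
#' Spectrum-interpolation notch: energy within +/-`notch_halfwidth` Hz of the
#' line frequency and its harmonics is replaced by the level of the
#' neighbouring spectrum, leaving the passband untouched.
#'
#' @param recording an [lfp_recording()] or [epoched_recording()].
#' @param config a [preprocess_config()].
#' @return The recording with line components attenuated.
#' @export
remove_line_noise <- function(recording, config = preprocess_config()) {
  if (recording$fs <= 2 * config$line_freq) {
    stop_invalid("sampling rate too low for line-noise removal")
  }
  apply_trace_matrix(recording, function(M, fs) {
    notch_matrix(M, fs, config$line_freq, config$n_harmonics,
                 config$notch_halfwidth)
  })
}

# map a (samples x traces matrix, fs) -> matrix function over either
# container type; batching traces keeps the FFT work vectorized
apply_trace_matrix <- function(recording, fun) {
  if (inherits(recording, "lfp_recording")) {
    recording$data <- t(fun(t(recording$data), recording$fs))
    recording
  } else if (inherits(recording, "epoched_recording")) {
    d <- dim(recording$data)
    out <- NULL
    for (ci in seq_len(d[2])) {
      res <- fun(contact_segment(recording, ci, seq_len(d[3])),
                 recording$fs)
      if (is.null(out)) out <- array(0, dim = c(d[1], d[2], nrow(res)))
      out[, ci, ] <- t(res)
    }
    recording$data <- out
    recording
  } else {
    stop_invalid("unsupported recording class")
  }
}

#' Resample a recording
#'
#' Anti-aliased Fourier-domain resampling to `target_rate`; non-integer rate
#' ratios (e.g. 2034.5 to 1000 Hz) are handled directly since only the
#' output sample count matters.
#'
#' @param recording an [lfp_recording()] or [epoched_recording()].
#' @param target_rate new sampling rate in Hz; must not exceed the current
#'   rate.
#' @return The resampled recording.
#' @export
resample_recording <- function(recording, target_rate) {
  if (target_rate > recording$fs) {
    stop_invalid("target_rate must not exceed the current sampling rate")
  }
  ratio <- target_rate / recording$fs
  if (inherits(recording, "lfp_recording")) {
    n_out <- round(ncol(recording$data) * ratio)
    recording$data <- t(fft_resample_cols(t(recording$data), n_out))
    recording$fs <- target_rate
    recording
  } else if (inherits(recording, "epoched_recording")) {
    n_out <- round(dim(recording$data)[3] * ratio)
    res <- apply_trace_matrix(recording, function(M, fs) {
      fft_resample_cols(M, n_out)
    })
    times <- seq(recording$times[1], by = 1 / target_rate,
                 length.out = n_out)
    epoched_recording(res$data, target_rate, times, recording$conditions,
                      recording$durations, recording$contact_ids)
  } else {
    stop_invalid("unsupported recording class")
  }
}

#' Cut a continuous recording into epochs
#'
#' Epochs are half-open `[start, stop)` on the sample grid with the onset
#' sample at t = 0. Onsets whose epoch would extend beyond the recording are
#' rejected with a warning.
#'
#' @param recording an [lfp_recording()].
#' @param onsets stimulus onset times in seconds (same clock as the
#'   recording).
#' @param window epoch limits c(start, stop) relative to each onset, s.
#' @param conditions optional per-onset condition labels.
#' @param durations optional per-onset stimulus durations, s.
#' @return An [epoched_recording()]; zero onsets give an empty epoch set.
#' @export
epoch_recording <- function(recording, onsets, window = c(-1.5, 6.3),
                            conditions = NULL, durations = NULL) {
  stopifnot(inherits(recording, "lfp_recording"), window[1] < window[2])
  fs <- recording$fs
  n_total <- ncol(recording$data)
  n_samp <- round((window[2] - window[1]) * fs)
  times <- seq(window[1], by = 1 / fs, length.out = n_samp)
  start_idx <- round((onsets - recording$start_time + window[1]) * fs) + 1
  ok <- start_idx >= 1 & (start_idx + n_samp - 1) <= n_total
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) rejected: epoch outside recording bounds")
  }
  keep <- which(ok)
  out <- array(0, dim = c(length(keep), nrow(recording$data), n_samp))
  for (i in seq_along(keep)) {
    idx <- start_idx[keep[i]]:(start_idx[keep[i]] + n_samp - 1)
    out[i, , ] <- recording$data[, idx, drop = FALSE]
  }
  epoched_recording(
    out, fs, times,
    if (is.null(conditions)) "trial" else conditions[keep],
    if (is.null(durations)) NULL else durations[keep],
    recording$contact_ids
  )
}
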