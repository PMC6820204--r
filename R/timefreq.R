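# Morlet wavelet time-frequency power. Low frequencies (2-30 Hz, 0.2 Hz
# steps) use wavelets whose length increases linearly from 3 to 12 cycles
# across the range; high frequencies (40-180 Hz, 1 Hz steps) use 12 cycles
# throughout. Power is the squared magnitude of the complex coefficients,
# averaged across trials, and expressed in dB relative to the mean power in
# a prestimulus baseline window.

#' Wavelet analysis configuration
#'
#' @param low_range,low_step low-frequency band limits and step, Hz.
#' @param low_cycles wavelet length in cycles at the low band's endpoints;
#'   interpolated linearly in between.
#' @param high_range,high_step high-frequency band limits and step, Hz.
#' @param high_cycles wavelet length (cycles) across the high band.
#' @param time_step hop of the output time grid, s; the grid is aligned so
#'   t = 0 is a grid point and windows include both endpoints.
#' @param analysis_window output window relative to stimulus onset, s.
#' @param baseline_window dB-baseline window, s; must precede 0.
#' @return A `wavelet_config` list.
#' @export
wavelet_config <- function(low_range = c(2, 30), low_step = 0.2,
                           low_cycles = c(3, 12),
                           high_range = c(40, 180), high_step = 1,
                           high_cycles = 12,
                           time_step = 0.010,
                           analysis_window = c(-0.6, 1.2),
                           baseline_window = c(-0.6, -0.1)) {
  stopifnot(low_step > 0, high_step > 0, time_step > 0,
            analysis_window[1] < analysis_window[2])
  if (baseline_window[2] > 0) {
    stop_invalid("baseline window must precede stimulus onset")
  }
  low_freqs <- seq(low_range[1], low_range[2], by = low_step)
  high_freqs <- seq(high_range[1], high_range[2], by = high_step)
  cyc <- low_cycles[1] + (low_cycles[2] - low_cycles[1]) *
    (low_freqs - low_range[1]) / (low_range[2] - low_range[1])
  structure(list(
    low_freqs = low_freqs, low_cycles_vec = cyc,
    high_freqs = high_freqs,
    high_cycles_vec = rep(high_cycles, length(high_freqs)),
    time_step = time_step, analysis_window = analysis_window,
    baseline_window = baseline_window
  ), class = "wavelet_config")
}

# complex Morlet wavelet at frequency f with the given number of cycles,
# sampled at fs; support +/- 3.5 temporal SDs. Unit-energy up to a fixed
# rate factor (sum |w|^2 = 1/fs) chosen so that coefficient power estimates
# spectral density and is invariant to the internal sampling rate: for
# white noise of variance sigma^2 at rate fs0, E|c|^2 = sigma^2/fs0 at
# every analysis frequency and rate.
morlet_wavelet <- function(f, cycles, fs) {
  sigma_t <- cycles / (2 * pi * f)
  half <- ceiling(3.5 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * exp(1i * 2 * pi * f * t)
  w / sqrt(sum(Mod(w)^2) * fs)
}

# decimation rate for a band: a divisor of fs, commensurate with the hop,
# comfortably above twice the band's top frequency plus wavelet bandwidth
pick_decimated_rate <- function(fs, time_step, fmax, cycles_at_fmax) {
  need <- 2.2 * fmax * (1 + 3 / cycles_at_fmax)
  divisors <- fs / seq_len(floor(fs))
  ok <- divisors[abs(divisors - round(divisors)) < .grid_eps]
  ok <- ok[abs(ok * time_step - round(ok * time_step)) < .grid_eps]
  ok <- sort(unique(round(ok)))
  cand <- ok[ok >= need]
  if (!length(cand)) fs else min(cand)
}

# FFT-resample the columns of a matrix to n_out rows (n_out <= n)
fft_resample_cols <- function(X, n_out) {
  n <- nrow(X)
  S <- mvfft(X)
  Sd <- matrix(0i, n_out, ncol(X))
  nh <- floor((n_out - 1) / 2)
  Sd[1, ] <- S[1, ]
  if (nh > 0) {
    Sd[2:(nh + 1), ] <- S[2:(nh + 1), , drop = FALSE]
    Sd[n_out - (1:nh) + 1, ] <- S[n - (1:nh) + 1, , drop = FALSE]
  }
  Re(mvfft(Sd, inverse = TRUE)) * (n_out / n) / n_out
}

# core convolution for one frequency band; returns contacts x freqs x times
morlet_band_power <- function(epochs, freqs, cycles, t_out) {
  d <- dim(epochs$data)
  n_trials <- d[1]; n_contacts <- d[2]
  fs <- epochs$fs
  sigma_t <- cycles / (2 * pi * freqs)
  pad <- 3.5 * max(sigma_t)
  fs_d <- pick_decimated_rate(fs, diff(t_out[1:2]), max(freqs),
                              cycles[which.max(freqs)])
  # segment of the epoch actually needed, snapped to the decimated grid
  pad_d <- ceiling(pad * fs_d) / fs_d
  seg_t0 <- t_out[1] - pad_d
  seg_t1 <- t_out[length(t_out)] + pad_d
  if (seg_t0 < min(epochs$times) - .grid_eps ||
      seg_t1 > max(epochs$times) + 1 / fs + .grid_eps) {
    worst <- freqs[which.max(sigma_t)]
    stop_invalid("analysis window too close to the epoch edge for the ",
                 worst, " Hz wavelet (needs [", round(seg_t0, 3), ", ",
                 round(seg_t1, 3), "] s)")
  }
  i0 <- round((seg_t0 - epochs$times[1]) * fs) + 1
  i1 <- round((seg_t1 - epochs$times[1]) * fs) + 1
  i1 <- min(i1, d[3])
  seg_len <- i1 - i0 + 1
  # columns ordered trial-fastest within contact
  M <- matrix(aperm(epochs$data[, , i0:i1, drop = FALSE], c(3, 1, 2)),
              seg_len, n_trials * n_contacts)
  n_dec <- round(seg_len * fs_d / fs)
  if (fs_d < fs) M <- fft_resample_cols(M, n_dec) else n_dec <- seg_len
  max_half <- ceiling(3.5 * max(sigma_t) * fs_d)
  nfft <- next_fft_size(n_dec + 2 * max_half + 1)
  S <- mvfft(rbind(M, matrix(0, nfft - n_dec, ncol(M))))
  j_out <- round((t_out - seg_t0) * fs_d) + 1
  avg <- matrix(0, n_trials * n_contacts, n_contacts)
  avg[cbind(seq_len(n_trials * n_contacts),
            rep(seq_len(n_contacts), each = n_trials))] <- 1 / n_trials
  power <- array(NA_real_, dim = c(n_contacts, length(freqs), length(t_out)))
  for (fi in seq_along(freqs)) {
    w <- morlet_wavelet(freqs[fi], cycles[fi], fs_d)
    half <- (length(w) - 1) / 2
    wv <- complex(length.out = nfft)
    wv[c((nfft - half + 1):nfft, 1:(half + 1))] <- w  # center at index 1
    Wf <- fft(wv)
    coef <- mvfft(S * Conj(Wf), inverse = TRUE)[j_out, , drop = FALSE] / nfft
    power[, fi, ] <- t(Mod(coef)^2 %*% avg)
  }
  power
}

#' Morlet wavelet time-frequency power
#'
#' Computes trial-averaged squared-magnitude Morlet coefficients on the
#' configured frequency grids over `config$analysis_window` in
#' `config$time_step` hops. Internally each band is processed at a reduced
#' sampling rate sufficient for its top frequency, which leaves the
#' coefficients unchanged (band-limited resampling) while keeping the
#' convolution cheap.
#'
#' @param epochs an [epoched_recording()]; must extend beyond the analysis
#'   window by at least half the longest wavelet.
#' @param config a [wavelet_config()].
#' @param freq_range optional c(lo, hi) restriction of the frequency grids,
#'   Hz.
#' @return A `tf_power`: `power` (contacts x frequencies x times, raw
#'   units), `freqs`, `times`, `units = "raw"`, `n_trials`, `contact_ids`.
#' @export
morlet_power <- function(epochs, config = wavelet_config(),
                         freq_range = NULL) {
  stopifnot(inherits(epochs, "epoched_recording"),
            inherits(config, "wavelet_config"))
  step <- config$time_step
  k <- ceiling(config$analysis_window[1] / step - .grid_eps):
    floor(config$analysis_window[2] / step + .grid_eps)
  t_out <- k * step
  bands <- list(
    list(freqs = config$low_freqs, cycles = config$low_cycles_vec),
    list(freqs = config$high_freqs, cycles = config$high_cycles_vec)
  )
  power <- NULL
  freqs <- numeric(0)
  for (b in bands) {
    sel <- seq_along(b$freqs)
    if (!is.null(freq_range)) {
      sel <- which(b$freqs >= freq_range[1] - .grid_eps &
                     b$freqs <= freq_range[2] + .grid_eps)
    }
    if (!length(sel)) next
    p <- morlet_band_power(epochs, b$freqs[sel], b$cycles[sel], t_out)
    power <- if (is.null(power)) p else {
      abind3(power, p)
    }
    freqs <- c(freqs, b$freqs[sel])
  }
  if (is.null(power)) stop_invalid("freq_range excludes every frequency")
  structure(list(power = power, freqs = freqs, times = t_out,
                 units = "raw", n_trials = dim(epochs$data)[1],
                 contact_ids = epochs$contact_ids,
                 baseline = NULL),
            class = "tf_power")
}

# bind two contacts x freqs x times arrays along the frequency axis
abind3 <- function(a, b) {
  out <- array(NA_real_, dim = c(dim(a)[1], dim(a)[2] + dim(b)[2], dim(a)[3]))
  out[, seq_len(dim(a)[2]), ] <- a
  out[, dim(a)[2] + seq_len(dim(b)[2]), ] <- b
  out
}

#' Decibel baseline correction
#'
#' Divides power at each time point by the mean power in the baseline
#' window (per contact and frequency) and converts to decibels:
#' dB(t, f) = 10 log10(P(t, f) / Pbar(f)).
#'
#' @param tf a raw `tf_power` from [morlet_power()].
#' @param baseline_window baseline limits in seconds.
#' @return A `tf_power` in dB units; the baseline matrix is kept so the raw
#'   power can be recovered exactly.
#' @export
baseline_db <- function(tf, baseline_window = c(-0.6, -0.1)) {
  stopifnot(inherits(tf, "tf_power"))
  if (tf$units != "raw") stop_invalid("dB conversion applied twice")
  b_idx <- time_index(tf$times, baseline_window[1], baseline_window[2])
  if (!length(b_idx)) stop_invalid("baseline window outside analysis window")
  pbar <- apply(tf$power[, , b_idx, drop = FALSE], c(1, 2), mean)
  if (any(pbar <= 0)) {
    stop_invalid("zero baseline power; cannot baseline-correct")
  }
  tf$power <- 10 * log10(sweep(tf$power, c(1, 2), pbar, "/"))
  tf$units <- "dB"
  tf$baseline <- pbar
  tf
}

#' Undo decibel baseline correction
#'
#' Inverse of [baseline_db()]: raw = 10^(dB/10) * Pbar.
#'
#' @param tf a dB `tf_power` carrying its baseline matrix.
#' @return The raw-power `tf_power`.
#' @export
undo_baseline_db <- function(tf) {
  stopifnot(inherits(tf, "tf_power"), tf$units == "dB",
            !is.null(tf$baseline))
  tf$power <- sweep(10^(tf$power / 10), c(1, 2), tf$baseline, "*")
  tf$units <- "raw"
  tf$baseline <- NULL
  tf
}

#' Mean power in a frequency band and time window
#'
#' @param tf a `tf_power` (raw or dB).
#' @param band frequency band c(lo, hi), Hz; endpoints inclusive on the
#'   grid.
#' @param window time window c(from, to), s; endpoints inclusive.
#' @return Named per-contact vector of mean power.
#' @export
band_window_power <- function(tf, band = c(7, 10), window = c(0.5, 1.2)) {
  stopifnot(inherits(tf, "tf_power"))
  f_idx <- which(tf$freqs >= band[1] - .grid_eps &
                   tf$freqs <= band[2] + .grid_eps)
  t_idx <- time_index(tf$times, window[1], window[2])
  if (!length(f_idx) || !length(t_idx)) {
    stop_invalid("empty band/window selection")
  }
  out <- apply(tf$power[, f_idx, t_idx, drop = FALSE], 1, mean)
  stats::setNames(out, tf$contact_ids)
}

#' Sentence-offset-locked alpha power
#'
#' Re-epochs each trial around its sentence offset, computes wavelet power
#' restricted to the requested band, baseline-corrects against the
#' post-offset window and returns the mean dB in the pre-offset analysis
#' window. Trials whose sentence is shorter than the pre-offset window are
#' excluded with a warning.
#'
#' @param epochs an [epoched_recording()] with per-trial `durations`.
#' @param config a [wavelet_config()].
#' @param band frequency band, Hz.
#' @param analysis_window window relative to sentence offset, s.
#' @param baseline_window post-offset baseline window, s.
#' @return Named per-contact vector of offset-locked band power (dB).
#' @export
offset_locked_power <- function(epochs, config = wavelet_config(),
                                band = c(7, 10),
                                analysis_window = c(-1.2, -0.5),
                                baseline_window = c(0.1, 0.6)) {
  stopifnot(inherits(epochs, "epoched_recording"))
  if (is.null(epochs$durations)) {
    stop_invalid("offset-locked analysis needs per-trial sentence durations")
  }
  fs <- epochs$fs
  min_dur <- -analysis_window[1]
  ok <- epochs$durations >= min_dur
  if (!any(ok)) stop_invalid("no trials with sentences of at least ",
                             min_dur, " s")
  if (any(!ok)) {
    warning(sum(!ok), " trial(s) shorter than ", min_dur, " s excluded")
    epochs <- subset_trials(epochs, ok)
  }
  # re-epoch to offset: window wide enough for the band's longest wavelet
  cyc_min <- approx_cycles(config, band[1])
  pad <- ceiling(3.5 * cyc_min / (2 * pi * band[1]) * fs) / fs
  new_win <- c(analysis_window[1] - pad - 0.05, baseline_window[2] + pad + 0.05)
  d <- dim(epochs$data)
  n_samp <- round((new_win[2] - new_win[1]) * fs)
  times <- seq(new_win[1], by = 1 / fs, length.out = n_samp)
  out <- array(0, dim = c(d[1], d[2], n_samp))
  for (tr in seq_len(d[1])) {
    off_idx <- round((epochs$durations[tr] + new_win[1] - epochs$times[1]) * fs) + 1
    idx <- off_idx:(off_idx + n_samp - 1)
    if (idx[1] < 1 || idx[length(idx)] > d[3]) {
      stop_invalid("offset epoch outside recorded window for trial ", tr)
    }
    out[tr, , ] <- epochs$data[tr, , idx]
  }
  re <- epoched_recording(out, fs, times, epochs$conditions[seq_len(d[1])],
                          NULL, epochs$contact_ids)
  cfg <- config
  cfg$analysis_window <- c(analysis_window[1], baseline_window[2])
  tf <- morlet_power(re, cfg, freq_range = band)
  tf <- baseline_db(tf, baseline_window)
  band_window_power(tf, band, analysis_window)
}

# wavelet cycles at an arbitrary frequency under a config's rules
approx_cycles <- function(config, f) {
  if (f <= max(config$low_freqs) + .grid_eps) {
    stats::approx(config$low_freqs, config$low_cycles_vec, f, rule = 2)$y
  } else {
    config$high_cycles_vec[1]
  }
}
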