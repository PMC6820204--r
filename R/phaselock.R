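# Inter-trial phase coherence (ITPC) to click trains and its surrogate
# chance level. ITPC is the magnitude of the trial-mean of unit-normalized
# complex spectral coefficients: 0 = random phases, 1 = perfect locking.

#' Inter-trial phase coherence
#'
#' For each contact, an FFT (Hann taper, zero-padded to 1 Hz resolution) is
#' computed over the analysis window of every trial; each complex coefficient
#' is normalized by its magnitude and ITPC is the absolute value of the
#' trial mean of the normalized coefficients.
#'
#' The window is half-open `[from, to)` on the sample grid. Zero padding is
#' chosen so frequency bins fall on integer Hz, placing every click
#' repetition rate on an exact bin.
#'
#' @param epochs an [epoched_recording()].
#' @param window analysis window in seconds.
#' @param freq_range frequency range in Hz.
#' @param freq_resolution spacing of frequency bins after padding, Hz.
#' @return An `itpc_result`: `values` (contacts x frequencies, in \[0, 1\]),
#'   `freqs`, `window`, `n_trials`, and empty chance-level slots to be filled
#'   by [surrogate_chance_level()].
#' @export
compute_itpc <- function(epochs, window = c(0, 0.2), freq_range = c(20, 210),
                         freq_resolution = 1) {
  stopifnot(inherits(epochs, "epoched_recording"))
  d <- dim(epochs$data)
  if (d[1] < 2) stop_invalid("ITPC needs at least 2 trials")
  idx <- which(epochs$times >= window[1] - .grid_eps &
                 epochs$times < window[2] - .grid_eps)
  if (!length(idx)) stop_invalid("analysis window outside epoch")
  n_win <- length(idx)
  nfft <- round(epochs$fs / freq_resolution)
  stopifnot(nfft >= n_win)
  taper <- signal::hanning(n_win)
  freqs_all <- (seq_len(nfft) - 1) * epochs$fs / nfft
  sel <- which(freqs_all >= freq_range[1] - .grid_eps &
                 freqs_all <= freq_range[2] + .grid_eps)
  values <- matrix(NA_real_, d[2], length(sel),
                   dimnames = list(epochs$contact_ids, NULL))
  for (ci in seq_len(d[2])) {
    seg <- contact_segment(epochs, ci, idx)   # samples x trials
    nonzero <- colSums(seg != 0) > 0
    if (!all(nonzero)) {
      warning("contact ", epochs$contact_ids[ci], ": ", sum(!nonzero),
              " all-zero trial(s) excluded from ITPC")
      seg <- seg[, nonzero, drop = FALSE]
      if (ncol(seg) < 2) stop_invalid("fewer than 2 usable trials")
    }
    padded <- rbind(seg * taper,
                    matrix(0, nfft - n_win, ncol(seg)))
    Z <- mvfft(padded)[sel, , drop = FALSE]
    mag <- Mod(Z)
    U <- Z
    U[mag > 0] <- Z[mag > 0] / mag[mag > 0]
    U[mag == 0] <- 0
    values[ci, ] <- Mod(rowMeans(U))
  }
  structure(list(values = values, freqs = freqs_all[sel], window = window,
                 n_trials = d[1], chance_mean = NULL, chance_sd = NULL,
                 n_surrogates = 0L, contact_ids = epochs$contact_ids),
            class = "itpc_result")
}

# phase-randomize the columns of a real matrix (samples x trials),
# preserving each column's amplitude spectrum and Hermitian symmetry
phase_randomize <- function(seg) {
  n <- nrow(seg)
  X <- mvfft(seg)
  half <- floor((n - 1) / 2)              # bins with a conjugate partner
  if (half > 0) {
    phi <- matrix(runif(half * ncol(seg), 0, 2 * pi), half, ncol(seg))
    rot <- exp(1i * phi)
    X[2:(half + 1), ] <- X[2:(half + 1), ] * rot
    X[n - (1:half) + 1, ] <- Conj(X[2:(half + 1), , drop = FALSE])
  }
  Re(mvfft(X, inverse = TRUE)) / n
}

#' Surrogate ITPC chance level
#'
#' Each trial's analysis-window segment is converted to the frequency
#' domain, its phases are randomized (amplitude spectrum preserved), and the
#' segment is converted back to the time domain; ITPC is then computed on
#' the surrogate trials. The procedure is repeated `n_surrogates` times and
#' the surrogate ITPC values are averaged, yielding the chance level (their
#' spread is also returned for significance thresholds).
#'
#' @inheritParams compute_itpc
#' @param n_surrogates number of phase-randomized repetitions.
#' @param seed integer seed.
#' @return An `itpc_chance` list: `mean` and `sd` (contacts x frequencies,
#'   across surrogates), `freqs`, `n_surrogates`.
#' @export
surrogate_chance_level <- function(epochs, window = c(0, 0.2),
                                   freq_range = c(20, 210),
                                   n_surrogates = 100, seed = 1,
                                   freq_resolution = 1) {
  stopifnot(inherits(epochs, "epoched_recording"))
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  d <- dim(epochs$data)
  if (d[1] < 2) stop_invalid("ITPC needs at least 2 trials")
  idx <- which(epochs$times >= window[1] - .grid_eps &
                 epochs$times < window[2] - .grid_eps)
  n_win <- length(idx)
  nfft <- round(epochs$fs / freq_resolution)
  taper <- signal::hanning(n_win)
  freqs_all <- (seq_len(nfft) - 1) * epochs$fs / nfft
  sel <- which(freqs_all >= freq_range[1] - .grid_eps &
                 freqs_all <= freq_range[2] + .grid_eps)
  acc <- array(0, dim = c(d[2], length(sel), n_surrogates))
  pad <- matrix(0, nfft - n_win, d[1])
  half <- floor((n_win - 1) / 2)
  for (ci in seq_len(d[2])) {
    seg <- contact_segment(epochs, ci, idx)
    X0 <- mvfft(seg)                 # forward transform reused by surrogates
    for (s in seq_len(n_surrogates)) {
      X <- X0
      if (half > 0) {
        rot <- exp(1i * matrix(runif(half * d[1], 0, 2 * pi), half, d[1]))
        X[2:(half + 1), ] <- X[2:(half + 1), , drop = FALSE] * rot
        X[n_win - (1:half) + 1, ] <- Conj(X[2:(half + 1), , drop = FALSE])
      }
      sur <- Re(mvfft(X, inverse = TRUE)) / n_win
      Z <- mvfft(rbind(sur * taper, pad))[sel, , drop = FALSE]
      mag <- Mod(Z)
      U <- Z
      U[mag > 0] <- Z[mag > 0] / mag[mag > 0]
      U[mag == 0] <- 0
      acc[ci, , s] <- Mod(rowMeans(U))
    }
  }
  structure(list(mean = apply(acc, c(1, 2), mean),
                 sd = apply(acc, c(1, 2), sd),
                 freqs = freqs_all[sel], n_surrogates = n_surrogates,
                 contact_ids = epochs$contact_ids),
            class = "itpc_chance")
}

#' ITPC at the neural frequency of the click repetition rate
#'
#' @param result an `itpc_result` or `itpc_chance` object.
#' @param rate click repetition rate, Hz; must lie within the frequency
#'   range.
#' @param what for chance objects, which array to read.
#' @return Named per-contact vector at the frequency bin nearest `rate`.
#' @export
itpc_at_stimulus_rate <- function(result, rate, what = c("values", "mean", "sd")) {
  what <- match.arg(what)
  freqs <- result$freqs
  if (rate < min(freqs) - .grid_eps || rate > max(freqs) + .grid_eps) {
    stop_invalid("rate ", rate, " Hz outside the ITPC frequency range")
  }
  bin <- which.min(abs(freqs - rate))
  arr <- if (inherits(result, "itpc_result")) result$values else result[[what]]
  stats::setNames(arr[, bin], result$contact_ids)
}

#' Significant phase locking at a stimulus rate
#'
#' A contact is significantly phase-locked at `rate` when its empirical ITPC
#' exceeds the surrogate mean by more than `n_sd` surrogate standard
#' deviations at the corresponding frequency bin.
#'
#' @param itpc an `itpc_result`.
#' @param chance an `itpc_chance` from [surrogate_chance_level()].
#' @param rate stimulus rate, Hz.
#' @param n_sd significance threshold in surrogate SD units.
#' @return Named logical vector per contact.
#' @export
itpc_significant <- function(itpc, chance, rate, n_sd = 3) {
  stopifnot(identical(itpc$contact_ids, chance$contact_ids))
  emp <- itpc_at_stimulus_rate(itpc, rate)
  mu <- itpc_at_stimulus_rate(chance, rate, "mean")
  s <- itpc_at_stimulus_rate(chance, rate, "sd")
  emp > mu + n_sd * s
}
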