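# Shared fixtures: all data are generated in code at test time.

# reduced-size simulation for unit tests (2 hemispheres, short experiments);
# any field can be overridden
small_params <- function(...) {
  defaults <- list(
    n_hemispheres = 2, n_pm = 3, n_al = 3, n_other = 3,
    n_trials_per_condition = 8, n_click_trials = 20,
    click_rates = c(25, 100), sample_rate = 1000, seed = 11
  )
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

# epoched recording holding identical copies of a deterministic waveform
tone_epochs <- function(freq, n_trials = 4, fs = 1000,
                        t_range = c(-1.5, 6.3), amp = 1, phase = 0,
                        noise_sd = 0) {
  n <- round(diff(t_range) * fs)
  tt <- seq(t_range[1], by = 1 / fs, length.out = n)
  x <- amp * cos(2 * pi * freq * tt + phase)
  data <- array(NA_real_, c(n_trials, 1, n))
  for (tr in seq_len(n_trials)) {
    data[tr, 1, ] <- x + if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
  }
  epoched_recording(data, fs, tt)
}

# white-noise epochs (random phases at every frequency)
noise_epochs <- function(n_trials, fs = 1000, t_range = c(-0.5, 0.5),
                         n_contacts = 1, sd = 1) {
  n <- round(diff(t_range) * fs)
  tt <- seq(t_range[1], by = 1 / fs, length.out = n)
  epoched_recording(array(rnorm(n_trials * n_contacts * n, 0, sd),
                          c(n_trials, n_contacts, n)), fs, tt)
}

# independent brute-force oracle for the exact signed-rank test: enumerates
# every sign assignment directly (no shared code with the implementation)
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_null <- apply(signs, 1, function(s) min(sum(r[s == 1]), total - sum(r[s == 1])))
  # two-sided: 2 * P(W <= w_obs) on the lower-tail statistic, capped at 1
  w_lower <- apply(signs, 1, function(s) sum(r[s == 1]))
  min(1, 2 * mean(w_lower <= w_obs + 1e-9))
}

# band energy fraction of a waveform via FFT (oracle for vocoder tests)
band_energy_fraction <- function(x, fs, band) {
  X <- Mod(fft(x))^2
  f <- abs(hgalpha:::fft_freqs(length(x), fs))
  sum(X[f >= band[1] & f <= band[2]]) / sum(X[f > 0.5])
}
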