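# Synthetic multi-hemisphere LFP generator. Emulates the statistical
# structure of depth-electrode recordings along Heschl's gyrus: a 1/f^chi
# scale-free background everywhere; strong ongoing ~8 Hz alpha on
# anterolateral (alHG) and lateral superior-temporal contacts that is
# multiplicatively suppressed during the sentence (more for clear than for
# vocoded speech, decaying with distance from the alHG centroid); high-gamma
# stimulus gain and short-latency broadband click responses on posteromedial
# (pmHG) contacts; and a slow, low-pass click response on alHG that cannot
# phase-lock above ~50 Hz.

#' Simulation parameters
#'
#' Defaults define the reference synthetic study: 8 hemispheres, pmHG and
#' alHG contact clusters plus scattered superior-temporal contacts, a
#' 1/f^2 background, an 8 Hz alpha oscillator that dominates alHG, and
#' condition-dependent multiplicative suppression (clear > vocoded) that
#' ramps in over 0.5 s after sentence onset, persists until offset, and
#' decays spatially as exp(-d/lambda).
#'
#' @param chi aperiodic 1/f exponent of the background.
#' @param alpha_freq alpha oscillator frequency, Hz.
#' @param alpha_amp_alHG,alpha_amp_pmHG,alpha_amp_other alpha amplitude by
#'   zone (alHG >> pmHG).
#' @param suppression_clear,suppression_vocoded fractional amplitude
#'   reduction of the alpha oscillator at the alHG centroid, per condition;
#'   clear must exceed vocoded.
#' @param suppression_ramp_time seconds after onset at which suppression
#'   reaches its plateau.
#' @param recovery_time seconds after sentence offset for suppression to
#'   release.
#' @param spatial_decay_lambda spatial decay constant of suppression, mm.
#' @param hg_response_amp amplitude of the 70-150 Hz stimulus-driven gain on
#'   pmHG contacts.
#' @param hg_band high-gamma band, Hz.
#' @param click_response_amp peak amplitude of click-evoked responses.
#' @param click_latency_pmHG,click_latency_alHG click response latencies in
#'   seconds; pmHG must be below 0.020 s.
#' @param click_locking_max_rate_alHG approximate upper rate limit (Hz) of
#'   alHG phase locking; sets the width of the slow alHG click kernel.
#' @param noise_sd standard deviation of the 1/f background.
#' @param n_hemispheres number of hemispheres.
#' @param n_pm,n_al,n_other contacts per hemisphere by zone.
#' @param n_trials_per_condition sentence trials per condition (clear,
#'   vocoded) per hemisphere.
#' @param n_click_trials click-train trials per rate.
#' @param click_rates click repetition rates simulated, Hz.
#' @param sentence_duration_range range of per-trial sentence durations, s.
#' @param epoch_window sentence epoch window relative to onset, s.
#' @param click_epoch_window click epoch window relative to train onset, s.
#' @param sample_rate acquisition sampling rate, Hz.
#' @param hemisphere_sd log-scale SD of per-hemisphere effect multipliers.
#' @param contact_sd log-scale SD of per-contact amplitude jitter.
#' @param seed integer seed; every random draw derives from it.
#' @return A validated `simulation_params` list.
#' @export
simulation_params <- function(chi = 2, alpha_freq = 8,
                              alpha_amp_alHG = 6, alpha_amp_pmHG = 0.8,
                              alpha_amp_other = 4,
                              suppression_clear = 0.6,
                              suppression_vocoded = 0.4,
                              suppression_ramp_time = 0.5,
                              recovery_time = 0.1,
                              spatial_decay_lambda = 20,
                              hg_response_amp = 0.2, hg_band = c(70, 150),
                              click_response_amp = 3,
                              click_latency_pmHG = 0.012,
                              click_latency_alHG = 0.030,
                              click_locking_max_rate_alHG = 50,
                              noise_sd = 1,
                              n_hemispheres = 8, n_pm = 5, n_al = 5,
                              n_other = 8,
                              n_trials_per_condition = 30,
                              n_click_trials = 50,
                              click_rates = c(25, 50, 100, 125, 150, 200),
                              sentence_duration_range = c(1.223, 4.703),
                              epoch_window = c(-1.5, 6.3),
                              click_epoch_window = c(-0.3, 0.5),
                              sample_rate = 2000,
                              hemisphere_sd = 0.12, contact_sd = 0.10,
                              seed = 1) {
  if (chi < 0) stop_invalid("chi must be non-negative")
  if (suppression_clear < 0 || suppression_clear >= 1 ||
      suppression_vocoded < 0 || suppression_vocoded >= 1) {
    stop_invalid("suppression fractions must lie in [0, 1)")
  }
  if (suppression_clear < suppression_vocoded) {
    stop_invalid("suppression_clear must be at least suppression_vocoded")
  }
  if (click_latency_pmHG >= 0.020) {
    stop_invalid("click_latency_pmHG must be below 0.020 s")
  }
  if (any(c(alpha_amp_alHG, alpha_amp_pmHG, alpha_amp_other,
            hg_response_amp, click_response_amp, noise_sd) < 0)) {
    stop_invalid("amplitudes must be non-negative")
  }
  if (n_trials_per_condition <= 0 || n_click_trials <= 0) {
    stop_invalid("trial counts must be positive")
  }
  if (n_hemispheres < 1 || n_pm < 1 || n_al < 1) {
    stop_invalid("need at least one hemisphere and one contact per HG zone")
  }
  structure(as.list(environment()), class = "simulation_params")
}

#' Build a synthetic contact set
#'
#' Places contacts in a simplified 3-D frame: pmHG and alHG clusters along a
#' gyrus axis plus scattered superior-temporal-plane / superior-temporal-gyrus
#' contacts with lateral offsets. `dist_alHG` is the Euclidean distance (mm)
#' to the mean alHG coordinate of the same hemisphere and is what drives the
#' spatial decay of simulated suppression. The `zone` column is ground truth
#' for validating localization; `hg` marks contacts anatomically on Heschl's
#' gyrus (the only anatomical information downstream analysis may use).
#'
#' @param params a [simulation_params()].
#' @param seed integer seed (defaults to the params seed).
#' @return A `contact_set` data.frame: contact_id, hemisphere_id, x, y, z,
#'   zone, hg, dist_alHG.
#' @export
make_contact_set <- function(params, seed = params$seed) {
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (h in seq_len(params$n_hemispheres)) {
    side <- if (h %% 2 == 1) "L" else "R"
    sgn <- if (side == "L") -1 else 1
    origin <- c(sgn * 42, -28, 12)
    u <- c(sgn * -0.45, 0.80, 0.40)            # posteromedial -> anterolateral
    u <- u / sqrt(sum(u^2))
    v <- c(sgn * 0.85, 0.45, 0.05)             # toward the lateral surface
    v <- v / sqrt(sum(v^2))
    place <- function(s, lat) {
      p <- outer(s, u) + outer(lat, v)
      sweep(p + matrix(rnorm(length(s) * 3, 0, 0.8), ncol = 3), 2, origin, "+")
    }
    n_pm <- params$n_pm; n_al <- params$n_al; n_ot <- params$n_other
    pm_xyz <- place(seq(0, 8, length.out = n_pm), numeric(n_pm))
    al_xyz <- place(seq(14, 24, length.out = n_al), numeric(n_al))
    ot_xyz <- if (n_ot > 0) {
      place(runif(n_ot, 4, 40), runif(n_ot, 6, 22))
    } else matrix(numeric(0), ncol = 3)
    xyz <- rbind(pm_xyz, al_xyz, ot_xyz)
    zone <- c(rep("pmHG", n_pm), rep("alHG", n_al), rep("other", n_ot))
    centroid <- colMeans(al_xyz)
    d <- sqrt(colSums((t(xyz) - centroid)^2))
    rows[[h]] <- data.frame(
      contact_id = sprintf("H%d_%s%02d", h, substr(zone, 1, 2),
                           seq_along(zone)),
      hemisphere_id = paste0("H", h), side = side,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      zone = zone, hg = zone != "other", dist_alHG = d,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("contact_set", "data.frame")
  out
}

#' Scale-free 1/f^chi background noise
#'
#' Gaussian noise whose mean power spectral density is proportional to
#' f^-chi (flat below `f_floor` to keep the variance finite). Generated by
#' spectrally shaping white Gaussian noise; the output is scaled analytically
#' (Parseval) so its expected standard deviation is `sd`.
#'
#' @param chi spectral exponent (>= 0).
#' @param n_samples samples per trace.
#' @param sample_rate sampling rate, Hz.
#' @param seed optional integer seed.
#' @param sd expected standard deviation of each trace.
#' @param n_traces number of independent traces.
#' @param f_floor frequency (Hz) below which the spectrum is flat.
#' @param pivot_hz optional pivot frequency: instead of fixing the total
#'   variance to `sd^2`, the spectrum is scaled so its density at
#'   `pivot_hz` is independent of `chi` (useful for slope-only
#'   manipulations that must leave the level at one frequency untouched).
#' @return A numeric vector (`n_traces = 1`) or an n_samples x n_traces
#'   matrix.
#' @export
spectral_background <- function(chi, n_samples, sample_rate, seed = NULL,
                                sd = 1, n_traces = 1, f_floor = 1,
                                pivot_hz = NULL) {
  if (chi < 0) stop_invalid("chi must be non-negative")
  if (!is.null(seed)) {
    old <- save_rng(); on.exit(restore_rng(old))
    set.seed(seed)
  }
  f <- abs(fft_freqs(n_samples, sample_rate))
  shape <- pmax(f, f_floor)^(-chi / 2)
  scale <- if (is.null(pivot_hz)) {
    sd / sqrt(mean(shape^2))
  } else {
    sd / max(pivot_hz, f_floor)^(-chi / 2)
  }
  w <- matrix(rnorm(n_samples * n_traces), n_samples, n_traces)
  x <- Re(mvfft(mvfft(w) * (shape * scale), inverse = TRUE)) / n_samples
  if (n_traces == 1) drop(x) else x
}

# band-limited Gaussian noise (brick-wall FFT mask), unit SD, one column per
# trace
bandlimited_noise <- function(band, n_samples, sample_rate, n_traces = 1) {
  f <- abs(fft_freqs(n_samples, sample_rate))
  mask <- as.numeric(f >= band[1] & f <= band[2])
  scale <- 1 / sqrt(mean(mask^2))
  w <- matrix(rnorm(n_samples * n_traces), n_samples, n_traces)
  x <- Re(mvfft(mvfft(w) * (mask * scale), inverse = TRUE)) / n_samples
  if (n_traces == 1) drop(x) else x
}

# Click-evoked kernels, peak-normalized to 1.
# pmHG: fast damped biphasic deflection (~2 ms lobes) with broadband energy
# well past 200 Hz. alHG: a slow half-cosine bump whose width is set by the
# locking rate limit, so its spectrum has a null near and above that rate.
click_kernel <- function(fs, type = c("pm", "al"), max_rate = 50) {
  type <- match.arg(type)
  if (type == "pm") {
    t <- seq(0, 0.010, by = 1 / fs)
    k <- sin(2 * pi * t / 0.004) * exp(-t / 0.002)
  } else {
    width <- 1 / max_rate            # 20 ms bump for a 50 Hz limit
    t <- seq(0, 2 * width, by = 1 / fs)
    k <- sin(pi * t / (2 * width))^2
  }
  k / max(abs(k))
}

# suppression time profile s(t): 0 before onset, linear ramp to 1 by
# ramp_time, plateau until the sentence offset, release over recovery_time
suppression_profile <- function(times, duration, ramp_time, recovery_time) {
  s <- numeric(length(times))
  up <- times > 0 & times < ramp_time
  s[up] <- times[up] / ramp_time
  s[times >= ramp_time & times <= duration] <- 1
  rel <- times > duration & times < duration + recovery_time
  s[rel] <- 1 - (times[rel] - duration) / recovery_time
  s
}

#' Simulate one hemisphere
#'
#' Generates the click-train experiment and the sentence experiment for the
#' contacts of a single hemisphere. See [simulation_params()] for the model.
#'
#' @param params a [simulation_params()].
#' @param contacts rows of a [make_contact_set()] result for one hemisphere.
#' @param seed integer seed for this hemisphere.
#' @return A list with elements `click` and `sentence`, both
#'   [epoched_recording()] objects at `params$sample_rate`.
#' @export
simulate_hemisphere <- function(params, contacts, seed) {
  stopifnot(length(unique(contacts$hemisphere_id)) == 1)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(seed)
  fs <- params$sample_rate
  n_contacts <- nrow(contacts)

  # per-hemisphere and per-contact effect multipliers
  hem_alpha <- exp(rnorm(1, 0, params$hemisphere_sd))
  hem_supp <- exp(rnorm(1, 0, params$hemisphere_sd))
  hem_hg <- exp(rnorm(1, 0, params$hemisphere_sd))
  contact_mult <- exp(rnorm(n_contacts, 0, params$contact_sd))
  zone_amp <- c(pmHG = params$alpha_amp_pmHG, alHG = params$alpha_amp_alHG,
                other = params$alpha_amp_other)
  alpha_amp <- zone_amp[contacts$zone] * hem_alpha * contact_mult
  # suppression fraction at each contact, capped below 1
  supp_at <- function(s_cond) {
    pmin(s_cond * hem_supp, 0.95) * exp(-contacts$dist_alHG /
                                          params$spatial_decay_lambda)
  }

  ## ---- sentence experiment ----
  n_per <- params$n_trials_per_condition
  n_trials <- 2L * n_per
  conditions <- sample(rep(c("clear", "vocoded"), n_per))
  durations <- runif(n_trials, params$sentence_duration_range[1],
                     params$sentence_duration_range[2])
  win <- params$epoch_window
  n_samp <- round((win[2] - win[1]) * fs)
  times <- seq(win[1], by = 1 / fs, length.out = n_samp)
  s_cond <- ifelse(conditions == "clear", params$suppression_clear,
                   params$suppression_vocoded)
  # suppression time profile per trial (trials x samples)
  prof <- t(vapply(durations, suppression_profile, numeric(n_samp),
                   times = times, ramp_time = params$suppression_ramp_time,
                   recovery_time = params$recovery_time))
  hg_env <- t(vapply(durations, function(d) {
    suppression_profile(times, d, ramp_time = 0.05,
                        recovery_time = 0.05)
  }, numeric(n_samp)))

  sent <- array(0, dim = c(n_trials, n_contacts, n_samp))
  s_frac <- vapply(s_cond, supp_at, numeric(n_contacts))  # contacts x trials
  for (ci in seq_len(n_contacts)) {
    bg <- spectral_background(params$chi, n_samp, fs, sd = params$noise_sd,
                              n_traces = n_trials)
    phases <- runif(n_trials, 0, 2 * pi)
    osc <- cos(outer(phases, 2 * pi * params$alpha_freq * times, "+"))
    gain <- 1 - s_frac[ci, ] * prof     # trials x samples
    x <- t(bg) + alpha_amp[ci] * gain * osc
    if (contacts$zone[ci] == "pmHG" && params$hg_response_amp > 0) {
      hg <- bandlimited_noise(params$hg_band, n_samp, fs, n_trials)
      x <- x + params$hg_response_amp * hem_hg * hg_env * t(hg)
    }
    sent[, ci, ] <- x
  }
  sentence <- epoched_recording(sent, fs, times, conditions, durations,
                                contacts$contact_id)

  ## ---- click-train experiment ----
  cwin <- params$click_epoch_window
  n_csamp <- round((cwin[2] - cwin[1]) * fs)
  ctimes <- seq(cwin[1], by = 1 / fs, length.out = n_csamp)
  rates <- rep(params$click_rates, each = params$n_click_trials)
  n_ctrials <- length(rates)
  k_pm <- click_kernel(fs, "pm")
  k_al <- click_kernel(fs, "al", params$click_locking_max_rate_alHG)
  # evoked response template per rate and zone (identical across trials)
  response_for <- function(rate, kernel, latency) {
    n_clicks <- round(rate * 0.160)
    click_t <- (seq_len(n_clicks) - 1) / rate + latency
    r <- numeric(n_csamp)
    idx0 <- round((click_t - cwin[1]) * fs) + 1
    for (i0 in idx0) {
      ii <- i0:min(i0 + length(kernel) - 1, n_csamp)
      r[ii] <- r[ii] + kernel[seq_along(ii)]
    }
    r * params$click_response_amp
  }
  templ <- list(
    pm = lapply(params$click_rates, response_for, kernel = k_pm,
                latency = params$click_latency_pmHG),
    al = lapply(params$click_rates, response_for, kernel = k_al,
                latency = params$click_latency_alHG)
  )
  names(templ$pm) <- names(templ$al) <- as.character(params$click_rates)

  clk <- array(0, dim = c(n_ctrials, n_contacts, n_csamp))
  for (ci in seq_len(n_contacts)) {
    bg <- spectral_background(params$chi, n_csamp, fs, sd = params$noise_sd,
                              n_traces = n_ctrials)
    phases <- runif(n_ctrials, 0, 2 * pi)
    osc <- cos(outer(phases, 2 * pi * params$alpha_freq * ctimes, "+"))
    x <- t(bg) + alpha_amp[ci] * osc
    zone <- contacts$zone[ci]
    if (zone %in% c("pmHG", "alHG")) {
      tl <- if (zone == "pmHG") templ$pm else templ$al
      for (tr in seq_len(n_ctrials)) {
        x[tr, ] <- x[tr, ] + tl[[as.character(rates[tr])]]
      }
    }
    clk[, ci, ] <- x
  }
  click <- epoched_recording(clk, fs, ctimes, as.character(rates),
                             contact_ids = contacts$contact_id)

  list(click = click, sentence = sentence)
}

#' Simulate a complete multi-hemisphere dataset
#'
#' Runs [make_contact_set()] and [simulate_hemisphere()] for every
#' hemisphere. All randomness derives from `params$seed`, so two calls with
#' equal parameters return bit-identical arrays.
#'
#' @param params a [simulation_params()].
#' @return A list with `contacts` (full [make_contact_set()] table) and
#'   `hemispheres`, a named list of per-hemisphere `list(click, sentence)`
#'   recordings.
#' @export
simulate_dataset <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  contacts <- make_contact_set(params)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(params$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, params$n_hemispheres)
  hemis <- lapply(seq_len(params$n_hemispheres), function(h) {
    hc <- contacts[contacts$hemisphere_id == paste0("H", h), ]
    simulate_hemisphere(params, hc, sub_seeds[h])
  })
  names(hemis) <- paste0("H", seq_len(params$n_hemispheres))
  list(contacts = contacts, hemispheres = hemis)
}
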