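# End-to-end orchestration: simulate -> preprocess -> localize -> analyze ->
# test -> report. Region labels used anywhere downstream come from the
# functional localization stage, never from simulation ground truth; all
# randomness flows from the single run seed.

#' Pipeline run configuration
#'
#' Collects every analysis constant: simulation parameters, wavelet setup,
#' analysis windows (stimulus-locked alpha 0.5-1.2 s against the -0.6 to
#' -0.1 s baseline; offset-locked -1.2 to -0.5 s against 0.1-0.6 s
#' post-offset), frequency bands (alpha 7-10 Hz, high gamma 70-150 Hz) and
#' statistics settings.
#'
#' @param sim a [simulation_params()].
#' @param wavelet a [wavelet_config()].
#' @param preprocess a [preprocess_config()].
#' @param localization a [localization_config()].
#' @param alpha_band,hg_band analysis bands, Hz.
#' @param stim_window stimulus-locked alpha analysis window, s.
#' @param hg_window stimulus-locked high-gamma analysis window, s.
#' @param prestim_window prestimulus window (also the dB baseline), s.
#' @param offset_window,offset_baseline offset-locked analysis and baseline
#'   windows, s (relative to sentence offset).
#' @param n_perm permutations for per-hemisphere trial-label tests.
#' @param q FDR level.
#' @param seed run seed; defaults to the simulation seed.
#' @param output_dir optional directory for CSV/log output.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = simulation_params(),
                       wavelet = wavelet_config(),
                       preprocess = preprocess_config(),
                       localization = localization_config(),
                       alpha_band = c(7, 10), hg_band = c(70, 150),
                       stim_window = c(0.5, 1.2), hg_window = c(0, 1.2),
                       prestim_window = c(-0.6, -0.1),
                       offset_window = c(-1.2, -0.5),
                       offset_baseline = c(0.1, 0.6),
                       n_perm = 1000, q = 0.05, seed = sim$seed,
                       output_dir = NULL) {
  if (stim_window[1] < prestim_window[2]) {
    stop_invalid("stimulus window must not overlap the prestimulus baseline")
  }
  if (offset_window[2] > offset_baseline[1]) {
    stop_invalid("offset window must precede its post-offset baseline")
  }
  rng <- range(c(wavelet$low_freqs, wavelet$high_freqs))
  if (alpha_band[1] < rng[1] || hg_band[2] > rng[2]) {
    stop_invalid("analysis bands must lie within the wavelet ranges")
  }
  structure(as.list(environment())[c(
    "sim", "wavelet", "preprocess", "localization", "alpha_band", "hg_band",
    "stim_window", "hg_window", "prestim_window", "offset_window",
    "offset_baseline", "n_perm", "q", "seed", "output_dir"
  )], class = "run_config")
}

# per-trial band power in dB: treats each trial as its own channel so the
# band-restricted wavelet pass yields single-trial power
trial_band_db <- function(epochs, config, band, window, baseline) {
  d <- dim(epochs$data)
  # (trials, contacts, samples) and (1, trials*contacts, samples) share the
  # same column-major layout, so this reshape is a relabeling, not a copy
  flat <- array(epochs$data, dim = c(1, d[1] * d[2], d[3]))
  fe <- epoched_recording(flat, epochs$fs, epochs$times, "trial", NULL,
                          paste0("tc", seq_len(d[1] * d[2])))
  cfg <- config
  cfg$analysis_window <- c(baseline[1], max(window[2], baseline[2]))
  tf <- morlet_power(fe, cfg, freq_range = band)
  tf <- baseline_db(tf, baseline)
  v <- band_window_power(tf, band, window)
  matrix(v, d[1], d[2])            # trials x contacts
}

mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_

#' Run the full analysis pipeline
#'
#' Simulates every hemisphere, preprocesses (line-noise removal and
#' resampling to the analysis rate), localizes HG contacts functionally,
#' computes stimulus- and offset-locked wavelet power, non-baselined band
#' power, spectral 1/f decompositions and the distance-decay regression,
#' and runs the group-level exact signed-rank tests. When
#' `config$output_dir` is set, tidy CSVs and a run log (seed and config
#' hash) are written there.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list; see the vignette for a tour.
#' @export
run_full_analysis <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  params <- config$sim
  contacts <- make_contact_set(params)
  old <- save_rng(); on.exit(restore_rng(old))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1, params$n_hemispheres * 3)
  hem_ids <- paste0("H", seq_len(params$n_hemispheres))

  loc_list <- list()
  hem_rows <- list()
  contact_rows <- list()
  perm_p <- numeric(0)

  for (h in seq_len(params$n_hemispheres)) {
    hid <- hem_ids[h]
    hc <- contacts[contacts$hemisphere_id == hid, ]
    rec <- simulate_hemisphere(params, hc, sub_seeds[h])

    ## preprocess (notch + downsample to the analysis rate)
    click <- preprocess_epochs(rec$click, config$preprocess)
    sent <- preprocess_epochs(rec$sentence, config$preprocess)
    rm(rec)

    ## localization (click experiment)
    click100 <- subset_trials(click, click$conditions == "100")
    itpc100 <- compute_itpc(click100)
    chance100 <- surrogate_chance_level(
      click100, n_surrogates = config$localization$n_surrogates,
      seed = sub_seeds[params$n_hemispheres + h])
    evoked <- averaged_evoked_potential(click)
    loc <- classify_contacts(itpc100, chance100, evoked, hc,
                             config$localization)
    loc_list[[hid]] <- loc
    assigned <- stats::setNames(loc$assigned, loc$contact_id)

    ## stimulus-locked wavelet power per condition
    tf_cond <- lapply(c(clear = "clear", vocoded = "vocoded"), function(cond) {
      morlet_power(subset_trials(sent, sent$conditions == cond),
                   config$wavelet)
    })
    tf_all <- tf_cond$clear
    tf_all$power <- (tf_cond$clear$power + tf_cond$vocoded$power) / 2
    db_all <- baseline_db(tf_all, config$prestim_window)
    db_cond <- lapply(tf_cond, baseline_db, config$prestim_window)

    alpha_db <- band_window_power(db_all, config$alpha_band,
                                  config$stim_window)
    hg_db <- band_window_power(db_all, config$hg_band, config$hg_window)
    alpha_db_cond <- lapply(db_cond, band_window_power,
                            band = config$alpha_band,
                            window = config$stim_window)
    raw_alpha_pre <- band_window_power(tf_all, config$alpha_band,
                                       config$prestim_window)
    raw_alpha_post <- band_window_power(tf_all, config$alpha_band,
                                        config$stim_window)
    raw_hg_pre <- band_window_power(tf_all, config$hg_band,
                                    config$prestim_window)
    raw_hg_post <- band_window_power(tf_all, config$hg_band,
                                     config$hg_window)
    offset_db <- offset_locked_power(sent, config$wavelet,
                                     config$alpha_band,
                                     config$offset_window,
                                     config$offset_baseline)

    ## per-trial alpha for the hemisphere-level label permutation
    trial_alpha <- trial_band_db(sent, config$wavelet, config$alpha_band,
                                 config$stim_window, config$prestim_window)
    pm_ids <- loc$contact_id[loc$assigned %in% "pmHG"]
    al_ids <- loc$contact_id[loc$assigned %in% "alHG"]
    pm_idx <- match(pm_ids, sent$contact_ids)
    al_idx <- match(al_ids, sent$contact_ids)
    perm_p[hid] <- if (length(pm_idx) && length(al_idx)) {
      trial_label_permutation(
        rowMeans(trial_alpha[, al_idx, drop = FALSE]),
        rowMeans(trial_alpha[, pm_idx, drop = FALSE]),
        n_perm = config$n_perm,
        seed = sub_seeds[2 * params$n_hemispheres + h])$p
    } else NA_real_

    ## spectral decomposition on region-mean spectra
    spec_pre <- window_spectrum(sent, config$prestim_window)
    spec_post <- window_spectrum(sent, config$stim_window)
    region_spec <- function(spec, ids) {
      colMeans(spec$power[match(ids, spec$contact_ids), , drop = FALSE])
    }
    decomp <- list()
    for (reg in c("pmHG", "alHG")) {
      ids <- if (reg == "pmHG") pm_ids else al_ids
      for (win in c("pre", "post")) {
        sp <- if (win == "pre") spec_pre else spec_post
        decomp[[paste(reg, win, sep = "_")]] <-
          decompose_spectrum(region_spec(sp, ids), sp$freqs,
                             alpha_band = config$alpha_band)
      }
    }

    region_mean <- function(v, ids) mean_or_na(v[ids])
    hem_rows[[hid]] <- data.frame(
      hemisphere_id = hid,
      alpha_db_pm = region_mean(alpha_db, pm_ids),
      alpha_db_al = region_mean(alpha_db, al_ids),
      alpha_db_pm_clear = region_mean(alpha_db_cond$clear, pm_ids),
      alpha_db_pm_vocoded = region_mean(alpha_db_cond$vocoded, pm_ids),
      alpha_db_al_clear = region_mean(alpha_db_cond$clear, al_ids),
      alpha_db_al_vocoded = region_mean(alpha_db_cond$vocoded, al_ids),
      hg_db_pm = region_mean(hg_db, pm_ids),
      hg_db_al = region_mean(hg_db, al_ids),
      offset_db_pm = region_mean(offset_db, pm_ids),
      offset_db_al = region_mean(offset_db, al_ids),
      raw_alpha_pre_pm = region_mean(raw_alpha_pre, pm_ids),
      raw_alpha_pre_al = region_mean(raw_alpha_pre, al_ids),
      raw_alpha_post_pm = region_mean(raw_alpha_post, pm_ids),
      raw_alpha_post_al = region_mean(raw_alpha_post, al_ids),
      raw_hg_pre_pm = region_mean(raw_hg_pre, pm_ids),
      raw_hg_pre_al = region_mean(raw_hg_pre, al_ids),
      raw_hg_post_pm = region_mean(raw_hg_post, pm_ids),
      raw_hg_post_al = region_mean(raw_hg_post, al_ids),
      slope_pre_pm = decomp$pmHG_pre$slope,
      slope_post_pm = decomp$pmHG_post$slope,
      slope_pre_al = decomp$alHG_pre$slope,
      slope_post_al = decomp$alHG_post$slope,
      nb_alpha_pre_pm = decomp$pmHG_pre$alpha_narrowband,
      nb_alpha_post_pm = decomp$pmHG_post$alpha_narrowband,
      nb_alpha_pre_al = decomp$alHG_pre$alpha_narrowband,
      nb_alpha_post_al = decomp$alHG_post$alpha_narrowband
    )
    contact_rows[[hid]] <- data.frame(
      hemisphere_id = hid, contact_id = names(alpha_db),
      assigned = unname(assigned[names(alpha_db)]),
      alpha_db = unname(alpha_db), hg_db = unname(hg_db),
      offset_alpha_db = unname(offset_db)
    )
  }

  localization <- do.call(rbind, loc_list)
  rownames(localization) <- NULL
  hem <- do.call(rbind, hem_rows)
  rownames(hem) <- NULL
  contact_table <- do.call(rbind, contact_rows)
  rownames(contact_table) <- NULL

  ## group-level tests
  tests <- list(
    alpha_alHG_vs_pmHG = exact_signed_rank(hem$alpha_db_al, hem$alpha_db_pm),
    alpha_offset_alHG_vs_pmHG = exact_signed_rank(hem$offset_db_al,
                                                  hem$offset_db_pm),
    hg_pmHG_vs_alHG = exact_signed_rank(hem$hg_db_pm, hem$hg_db_al),
    alpha_clear_vs_vocoded_alHG = exact_signed_rank(hem$alpha_db_al_clear,
                                                    hem$alpha_db_al_vocoded),
    alpha_clear_vs_vocoded_pmHG = exact_signed_rank(hem$alpha_db_pm_clear,
                                                    hem$alpha_db_pm_vocoded),
    raw_alpha_prestim_alHG_vs_pmHG = exact_signed_rank(hem$raw_alpha_pre_al,
                                                       hem$raw_alpha_pre_pm),
    raw_alpha_poststim_alHG_vs_pmHG = exact_signed_rank(hem$raw_alpha_post_al,
                                                        hem$raw_alpha_post_pm),
    raw_hg_prestim_pmHG_vs_alHG = exact_signed_rank(hem$raw_hg_pre_pm,
                                                    hem$raw_hg_pre_al),
    raw_hg_poststim_pmHG_vs_alHG = exact_signed_rank(hem$raw_hg_post_pm,
                                                     hem$raw_hg_post_al),
    slope_post_vs_pre_alHG = exact_signed_rank(hem$slope_post_al,
                                               hem$slope_pre_al),
    slope_post_vs_pre_pmHG = exact_signed_rank(hem$slope_post_pm,
                                               hem$slope_pre_pm),
    nb_alpha_pre_vs_post_alHG = exact_signed_rank(hem$nb_alpha_pre_al,
                                                  hem$nb_alpha_post_al),
    nb_alpha_pre_vs_post_pmHG = exact_signed_rank(hem$nb_alpha_pre_pm,
                                                  hem$nb_alpha_post_pm)
  )
  cm <- rbind(
    data.frame(hemisphere_id = hem$hemisphere_id, region = "pmHG",
               condition = "clear", value = hem$alpha_db_pm_clear),
    data.frame(hemisphere_id = hem$hemisphere_id, region = "pmHG",
               condition = "vocoded", value = hem$alpha_db_pm_vocoded),
    data.frame(hemisphere_id = hem$hemisphere_id, region = "alHG",
               condition = "clear", value = hem$alpha_db_al_clear),
    data.frame(hemisphere_id = hem$hemisphere_id, region = "alHG",
               condition = "vocoded", value = hem$alpha_db_al_vocoded)
  )
  tests$stimulus_by_region_interaction <- interaction_contrast(cm)

  assigned_all <- stats::setNames(localization$assigned,
                                  localization$contact_id)
  assigned_full <- stats::setNames(rep(NA_character_, nrow(contacts)),
                                   contacts$contact_id)
  assigned_full[names(assigned_all)] <- assigned_all
  alpha_all <- stats::setNames(contact_table$alpha_db,
                               contact_table$contact_id)
  distance <- distance_decay_fit(contacts, alpha_all, assigned_full)

  result <- structure(list(
    localization = localization,
    hemisphere_table = hem,
    contact_table = contact_table,
    tests = tests,
    test_table = test_results_table(tests, q = config$q),
    distance_decay = distance,
    hemisphere_permutation_p = perm_p,
    hemisphere_permutation_sig = fdr_correct(perm_p, config$q),
    config = config, seed = config$seed
  ), class = "pipeline_result")

  if (!is.null(config$output_dir)) write_pipeline_output(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", nrow(x$hemisphere_table), "hemispheres,",
      nrow(x$contact_table), "analyzed contacts\n")
  cat("group tests:\n")
  print(x$test_table, digits = 4)
  invisible(x)
}

# CSV + log outputs for a pipeline run
write_pipeline_output <- function(result) {
  dir <- result$config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$localization, file.path(dir, "localization.csv"),
            row.names = FALSE)
  write.csv(result$hemisphere_table, file.path(dir, "hemisphere_power.csv"),
            row.names = FALSE)
  write.csv(result$contact_table, file.path(dir, "contact_power.csv"),
            row.names = FALSE)
  write.csv(result$test_table, file.path(dir, "tests.csv"),
            row.names = FALSE)
  write.csv(result$distance_decay$per_hemisphere,
            file.path(dir, "distance_decay_slopes.csv"), row.names = FALSE)
  write.csv(result$distance_decay$contact_table,
            file.path(dir, "distance_decay_contacts.csv"), row.names = FALSE)
  cfg <- result$config
  cfg$output_dir <- NULL
  tmp <- tempfile()
  saveRDS(cfg, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  writeLines(c(
    paste("run at:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste("seed:", result$seed),
    paste("config md5:", hash)
  ), file.path(dir, "run_log.txt"))
  invisible(result)
}
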