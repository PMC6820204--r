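# Functional assignment of Heschl's gyrus contacts to the primary
# (posteromedial, pmHG) or non-primary (anterolateral, alHG) field. A
# contact is primary iff it shows (i) significant phase locking to 100 Hz
# click trains and (ii) a short-latency (< 20 ms) click-evoked component;
# HG contacts failing either criterion are assigned to alHG. Contacts off
# the gyrus are never classified.

#' Localization configuration
#'
#' @param rates click rate(s), Hz, at which significant phase locking is
#'   required (any-of). The standard criterion uses 100 Hz only.
#' @param latency_window window (s) in which an evoked component counts as
#'   short-latency.
#' @param threshold_sd evoked amplitude threshold in units of prestimulus
#'   SD.
#' @param itpc_sd ITPC significance threshold in surrogate SD units.
#' @param n_surrogates surrogate repetitions used for the chance level.
#' @return A `localization_config` list.
#' @export
localization_config <- function(rates = 100, latency_window = c(0, 0.020),
                                threshold_sd = 3, itpc_sd = 3,
                                n_surrogates = 100) {
  structure(list(rates = rates, latency_window = latency_window,
                 threshold_sd = threshold_sd, itpc_sd = itpc_sd,
                 n_surrogates = n_surrogates),
            class = "localization_config")
}

#' Averaged click-evoked potential
#'
#' Trial-mean voltage per contact, baseline-subtracted (mean over the
#' `baseline` window).
#'
#' @param epochs an [epoched_recording()] of click trials.
#' @param baseline baseline window in seconds.
#' @param min_trials minimum trial count.
#' @return An `evoked_potential`: `data` (contacts x samples), `times`,
#'   `fs`, `contact_ids`.
#' @export
averaged_evoked_potential <- function(epochs, baseline = c(-0.1, 0),
                                      min_trials = 10) {
  stopifnot(inherits(epochs, "epoched_recording"))
  if (dim(epochs$data)[1] < min_trials) {
    stop_invalid("need at least ", min_trials, " trials for an evoked average")
  }
  ev <- apply(epochs$data, c(2, 3), mean)
  b_idx <- time_index(epochs$times, baseline[1], baseline[2])
  if (!length(b_idx)) stop_invalid("baseline window outside epoch")
  ev <- ev - rowMeans(ev[, b_idx, drop = FALSE])
  structure(list(data = ev, times = epochs$times, fs = epochs$fs,
                 contact_ids = epochs$contact_ids),
            class = "evoked_potential")
}

#' Detect short-latency evoked components
#'
#' A component is detected when the absolute evoked voltage exceeds
#' `threshold_sd` times the prestimulus SD at any sample inside the latency
#' window; the latency is the first threshold crossing.
#'
#' @param evoked an `evoked_potential` from [averaged_evoked_potential()];
#'   must include at least 100 ms of prestimulus baseline.
#' @param threshold_sd amplitude threshold in prestimulus-SD units.
#' @param window latency window (s), open at 0.
#' @return data.frame: contact_id, short_latency (logical), latency (s; NA
#'   when no crossing).
#' @export
detect_short_latency <- function(evoked, threshold_sd = 3,
                                 window = c(0, 0.020)) {
  stopifnot(inherits(evoked, "evoked_potential"))
  if (min(evoked$times) > -0.1 + .grid_eps) {
    stop_invalid("evoked potential needs >= 100 ms of prestimulus baseline")
  }
  pre <- which(evoked$times < -.grid_eps)
  win <- which(evoked$times > .grid_eps &
                 evoked$times < window[2] - .grid_eps)
  res <- lapply(seq_len(nrow(evoked$data)), function(ci) {
    base_sd <- sd(evoked$data[ci, pre])
    if (base_sd == 0) stop_invalid("zero baseline variance at contact ",
                                   evoked$contact_ids[ci])
    over <- abs(evoked$data[ci, win]) > threshold_sd * base_sd
    if (any(over)) {
      data.frame(contact_id = evoked$contact_ids[ci], short_latency = TRUE,
                 latency = evoked$times[win[which(over)[1]]])
    } else {
      data.frame(contact_id = evoked$contact_ids[ci], short_latency = FALSE,
                 latency = NA_real_)
    }
  })
  do.call(rbind, res)
}

#' Classify HG contacts into pmHG and alHG
#'
#' Applies the two functional criteria (significant 100 Hz phase locking AND
#' a short-latency evoked component) to every contact marked as lying on
#' Heschl's gyrus; contacts meeting both are pmHG, the rest alHG. Non-HG
#' contacts are left unclassified.
#'
#' @param itpc an `itpc_result` for the click experiment.
#' @param chance the matching `itpc_chance`.
#' @param evoked the matching `evoked_potential`.
#' @param contacts a [make_contact_set()] table (or any data.frame with
#'   contact_id, hemisphere_id and hg columns) covering the same contacts.
#' @param config a [localization_config()].
#' @return A `localization_report` data.frame: contact_id, hemisphere_id,
#'   assigned ("pmHG"/"alHG"/NA for non-HG), itpc_significant,
#'   short_latency, evoked_latency.
#' @export
classify_contacts <- function(itpc, chance, evoked, contacts,
                              config = localization_config()) {
  if (!identical(itpc$contact_ids, evoked$contact_ids)) {
    stop_invalid("ITPC and evoked inputs cover different contacts")
  }
  if (!all(contacts$contact_id %in% itpc$contact_ids)) {
    stop_invalid("contact table does not match ITPC/evoked contacts")
  }
  sig <- Reduce(`|`, lapply(config$rates, function(r) {
    itpc_significant(itpc, chance, r, config$itpc_sd)
  }))
  lat <- detect_short_latency(evoked, config$threshold_sd,
                              config$latency_window)
  ord <- match(contacts$contact_id, itpc$contact_ids)
  out <- data.frame(
    contact_id = contacts$contact_id,
    hemisphere_id = contacts$hemisphere_id,
    itpc_significant = unname(sig[ord]),
    short_latency = lat$short_latency[ord],
    evoked_latency = lat$latency[ord],
    stringsAsFactors = FALSE
  )
  out$assigned <- ifelse(!contacts$hg, NA_character_,
                         ifelse(out$itpc_significant & out$short_latency,
                                "pmHG", "alHG"))
  class(out) <- c("localization_report", "data.frame")
  out
}
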