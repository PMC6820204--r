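#' Continuous multi-channel recording
#'
#' A thin container for a continuous local field potential recording:
#' a channels-by-samples matrix plus its sampling rate. Time zero is the
#' first sample unless `start_time` says otherwise.
#'
#' @param data numeric matrix, channels (rows) by samples (columns), or a
#'   vector for a single channel.
#' @param fs sampling rate in Hz.
#' @param start_time time of the first sample in seconds.
#' @param contact_ids optional character vector of channel names.
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(data, fs, start_time = 0, contact_ids = NULL) {
  if (is.vector(data)) data <- matrix(data, nrow = 1)
  stopifnot(is.matrix(data), fs > 0)
  if (is.null(contact_ids)) contact_ids <- paste0("ch", seq_len(nrow(data)))
  structure(
    list(data = data, fs = fs, start_time = start_time,
         contact_ids = contact_ids),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Epoched recording
#'
#' Trials x contacts x samples voltage array with a time axis relative to
#' stimulus onset and per-trial condition labels. For sentence experiments
#' `durations` holds the per-trial stimulus duration in seconds so analyses
#' can re-lock epochs to stimulus offset.
#'
#' @param data numeric array, trials x contacts x samples.
#' @param fs sampling rate in Hz.
#' @param times numeric vector of sample times in seconds relative to onset;
#'   length must equal `dim(data)[3]`.
#' @param conditions per-trial condition labels (character), recycled if
#'   length one.
#' @param durations optional per-trial stimulus duration in seconds.
#' @param contact_ids optional contact names.
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, times, conditions = "trial",
                              durations = NULL, contact_ids = NULL) {
  stopifnot(length(dim(data)) == 3, length(times) == dim(data)[3])
  if (anyNA(data)) stop_invalid("epoched data must not contain NA")
  n_trials <- dim(data)[1]
  conditions <- rep_len(as.character(conditions), n_trials)
  if (!is.null(durations)) durations <- rep_len(durations, n_trials)
  if (is.null(contact_ids)) contact_ids <- paste0("ch", seq_len(dim(data)[2]))
  structure(
    list(data = data, fs = fs, times = times, conditions = conditions,
         durations = durations, contact_ids = contact_ids),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording> %d trials x %d contacts x %d samples @ %g Hz, t in [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$fs, min(x$times), max(x$times)))
  cat("  conditions:", paste(names(table(x$conditions)), table(x$conditions),
                             sep = ":", collapse = ", "), "\n")
  invisible(x)
}

#' Subset trials of an epoched recording
#' @param epochs an [epoched_recording()].
#' @param i trial indices or a logical mask.
#' @return An `epoched_recording` with the selected trials.
#' @export
subset_trials <- function(epochs, i) {
  epoched_recording(
    epochs$data[i, , , drop = FALSE], epochs$fs, epochs$times,
    epochs$conditions[i],
    if (!is.null(epochs$durations)) epochs$durations[i],
    epochs$contact_ids
  )
}

# index range of `times` covering [from, to] inclusive (grid tolerance)
time_index <- function(times, from, to) {
  which(times >= from - .grid_eps & times <= to + .grid_eps)
}

# samples x trials matrix for one contact (robust to single-trial epochs)
contact_segment <- function(epochs, ci, idx) {
  m <- epochs$data[, ci, idx, drop = FALSE]
  dim(m) <- c(dim(m)[1], dim(m)[3])
  t(m)
}
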