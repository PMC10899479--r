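#' Construct an epoch set
#'
#' An `epoch_set` bundles per-feedback EEG epochs: a numeric array
#' `[epochs x channels x samples]` in microvolts, the sampling rate, the time
#' axis in seconds relative to feedback onset, ordered channel labels, one
#' event-metadata row per epoch, and per-epoch rejection flags.
#'
#' @param data Numeric array `[epochs x channels x samples]`.
#' @param sfreq Sampling rate in Hz.
#' @param times Numeric vector of sample times in seconds (strictly increasing,
#'   uniform); length must equal `dim(data)[3]`.
#' @param channels Character vector of channel labels; length `dim(data)[2]`.
#' @param events Data frame with one row per epoch (keys such as `dyad_id`,
#'   `participant_id`, `trial_index`, `feedback_index`, plus covariates).
#' @param rejected Logical vector per epoch (default all `FALSE`).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, times, channels, events,
                      rejected = rep(FALSE, dim(data)[1])) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(times) != dim(data)[3]) stop_config("times must match sample count")
  if (length(channels) != dim(data)[2]) stop_config("channels must match data")
  if (nrow(events) != dim(data)[1]) stop_config("events must have one row per epoch")
  dt <- diff(times)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    stop_config("times must be strictly increasing and uniform")
  }
  structure(list(data = data, sfreq = sfreq, times = as.numeric(times),
                 channels = as.character(channels), events = events,
                 rejected = as.logical(rejected)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$sfreq))
  cat(sprintf("  time %.3f .. %.3f s | channels: %s | rejected: %d\n",
              min(x$times), max(x$times), paste(x$channels, collapse = ", "),
              sum(x$rejected)))
  invisible(x)
}

#' Number of epochs in an epoch set
#' @param epochs An `epoch_set`.
#' @export
n_epochs <- function(epochs) dim(epochs$data)[1]

channel_index <- function(epochs, channel) {
  idx <- match(channel, epochs$channels)
  if (anyNA(idx)) {
    stop_config("unknown electrode label(s): ",
                paste(channel[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Subset an epoch set by epoch index
#' @param epochs An `epoch_set`.
#' @param keep Integer or logical index over epochs.
#' @export
subset_epochs <- function(epochs, keep) {
  epoch_set(epochs$data[keep, , , drop = FALSE], epochs$sfreq, epochs$times,
            epochs$channels, epochs$events[keep, , drop = FALSE],
            epochs$rejected[keep])
}

#' Cut epochs out of a continuous record and baseline-correct them
#'
#' Extracts `[tmin, tmax]` epochs around event onsets from a continuous
#' multichannel record and subtracts, per epoch and channel, the mean over the
#' baseline window. Events too close to the record edge are skipped with a
#' warning.
#'
#' @param record Numeric matrix `[channels x samples]` of the continuous signal.
#' @param sfreq Sampling rate in Hz.
#' @param onsets Event onset times in seconds from the start of the record.
#' @param events Data frame of event metadata, one row per onset.
#' @param channels Channel labels.
#' @param tmin,tmax Epoch window in seconds relative to onset.
#' @param baseline Length-2 numeric, baseline window in seconds (default
#'   `c(-0.1, 0)`); `NULL` skips baseline correction.
#' @return An `epoch_set`.
#' @export
epoch_and_baseline <- function(record, sfreq, onsets, events, channels,
                               tmin = -2, tmax = 2, baseline = c(-0.1, 0)) {
  stopifnot(is.matrix(record))
  n_samp <- ncol(record)
  rel_idx <- seq(round(tmin * sfreq), round(tmax * sfreq))
  times <- rel_idx / sfreq
  onset_idx <- round(onsets * sfreq) + 1L
  ok <- onset_idx + rel_idx[1] >= 1 & onset_idx + rel_idx[length(rel_idx)] <= n_samp
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the record edge were skipped")
  }
  onset_idx <- onset_idx[ok]
  dat <- array(NA_real_, dim = c(length(onset_idx), nrow(record), length(rel_idx)))
  for (e in seq_along(onset_idx)) {
    dat[e, , ] <- record[, onset_idx[e] + rel_idx, drop = FALSE]
  }
  out <- epoch_set(dat, sfreq, times, channels, events[ok, , drop = FALSE])
  if (!is.null(baseline)) out <- apply_baseline(out, baseline) else out
}

#' Subtract the per-epoch, per-channel baseline mean
#' @param epochs An `epoch_set`.
#' @param baseline Length-2 numeric window in seconds.
#' @export
apply_baseline <- function(epochs, baseline = c(-0.1, 0)) {
  sel <- epochs$times >= baseline[1] & epochs$times < baseline[2]
  if (!any(sel)) stop_config("baseline window contains no samples")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Write / read an epoch set as a plain-text container
#'
#' The container is a directory with `meta.json` (sampling rate, times,
#' channels, rejection flags), `events.csv`, and `data.csv` holding the array
#' flattened to one row per epoch x channel (columns = samples). The layout is
#' language-neutral and round-trips exactly to numeric precision.
#'
#' @param epochs An `epoch_set`.
#' @param path Directory to create/read.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` an `epoch_set`.
#' @export
write_epochs <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sfreq = epochs$sfreq, times = epochs$times,
               channels = epochs$channels, rejected = epochs$rejected,
               dim = dim(epochs$data))
  jsonlite::write_json(meta, file.path(path, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  utils::write.csv(epochs$events, file.path(path, "events.csv"), row.names = FALSE)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)),
                 nrow = dim(epochs$data)[1] * dim(epochs$data)[2], byrow = TRUE)
  utils::write.table(flat, file.path(path, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  events <- utils::read.csv(file.path(path, "events.csv"))
  flat <- as.matrix(utils::read.table(file.path(path, "data.csv"), sep = ","))
  dimnames(flat) <- NULL
  d <- meta$dim
  dat <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(dat, meta$sfreq, meta$times, meta$channels, events,
            as.logical(meta$rejected))
}
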