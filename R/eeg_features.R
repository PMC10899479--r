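#' Analysis windows and frequency bands
#'
#' ERP analysis windows (ms): 225-275, 275-350, 350-500, 500-700.
#' Time-frequency windows (ms): early 180-230, late 230-500.
#' Bands (Hz): theta 4-8, alpha 8-12, beta 12-30. Shared band edges (8, 12 Hz)
#' belong to the lower band (closed upper bound, open lower bound) so no grid
#' frequency is counted twice; time windows are half-open `[start, end)`.
#'
#' @name analysis-grid
NULL

#' @rdname analysis-grid
#' @export
erp_windows_ms <- function() {
  list("225-275" = c(225, 275), "275-350" = c(275, 350),
       "350-500" = c(350, 500), "500-700" = c(500, 700))
}

#' @rdname analysis-grid
#' @export
tf_windows_ms <- function() {
  list("180-230" = c(180, 230), "230-500" = c(230, 500))
}

#' @rdname analysis-grid
#' @export
freq_bands <- function() {
  list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30))
}

band_mask <- function(freqs, band, bands = freq_bands()) {
  lo <- bands[[band]][1]
  hi <- bands[[band]][2]
  # closed upper bound; lower bound open unless it is the lowest band edge
  lowest <- min(vapply(bands, `[`, numeric(1), 1))
  if (lo == lowest) freqs >= lo & freqs <= hi else freqs > lo & freqs <= hi
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window FIR design (via [signal::fir1()]) applied by linear
#' convolution with the group delay removed, giving an exactly zero-phase
#' pass. The signal mean is removed first, and edges are padded by reflection.
#'
#' @param record Numeric matrix `[channels x samples]` or a vector.
#' @param sfreq Sampling rate in Hz.
#' @param low_hz,high_hz Pass-band edges; `0 < low_hz < high_hz < sfreq / 2`.
#' @param order FIR order (even); default scales with the signal length.
#' @return Filtered record of the same shape.
#' @export
bandpass_filter <- function(record, sfreq, low_hz = 0.1, high_hz = 30,
                            order = NULL) {
  vec_in <- is.null(dim(record))
  if (vec_in) record <- matrix(record, nrow = 1)
  if (low_hz <= 0 || low_hz >= high_hz || high_hz >= sfreq / 2) {
    stop_config("need 0 < low_hz < high_hz < sfreq/2")
  }
  n <- ncol(record)
  if (is.null(order)) order <- min(2L * floor(n / 6), 512L)
  order <- max(2L, (order %/% 2L) * 2L)
  h <- signal::fir1(order, c(low_hz, high_hz) / (sfreq / 2), type = "pass")
  half <- order / 2
  out <- record
  for (ch in seq_len(nrow(record))) {
    x <- record[ch, ]
    mu <- mean(x)
    x <- x - mu
    pad <- c(rev(x[seq_len(half)]), x, rev(x[n - seq_len(half) + 1L]))
    y <- stats::filter(pad, h, method = "convolution", sides = 1)
    out[ch, ] <- as.numeric(y[(2 * half + 1):(2 * half + n)])
  }
  if (vec_in) out[1, ] else out
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Epochs with any sample whose absolute value exceeds `threshold_uv` on any
#' channel inside the inspection window are flagged rejected; feature
#' extractors exclude them. Lowering the threshold can only add rejections.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_uv Threshold in microvolts (default 100).
#' @param window Length-2 inspection window in seconds (default `c(-0.1, 1)`).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100, window = c(-0.1, 1.0)) {
  sel <- epochs$times >= window[1] & epochs$times <= window[2]
  if (!any(sel)) stop_config("inspection window outside the epoch")
  peak <- apply(abs(epochs$data[, , sel, drop = FALSE]), 1, max)
  epochs$rejected <- epochs$rejected | peak > threshold_uv
  epochs
}

#' Mean ERP amplitude per analysis window and electrode
#'
#' The feature value is the arithmetic mean of the samples whose time lies in
#' `[start, end)` for the given electrode; one row per kept epoch x electrode
#' x window.
#'
#' @param epochs A baseline-corrected `epoch_set`.
#' @param windows Named list of windows in ms (default [erp_windows_ms()]).
#' @param electrodes Channel labels to analyze (default Fz, Cz, Pz).
#' @return Long data frame: event keys, `electrode`, `window`, `value` (uV),
#'   `feature_kind = "erp_mean"`.
#' @export
erp_window_means <- function(epochs, windows = erp_windows_ms(),
                             electrodes = c("Fz", "Cz", "Pz")) {
  ch_idx <- channel_index(epochs, electrodes)
  keep <- which(!epochs$rejected)
  rows <- vector("list", length(windows) * length(electrodes))
  i <- 0
  for (w in names(windows)) {
    sel <- epochs$times >= windows[[w]][1] / 1000 & epochs$times < windows[[w]][2] / 1000
    if (!any(sel)) stop_config("window ", w, " ms has no samples in the epoch")
    for (j in seq_along(electrodes)) {
      vals <- rowMeans(epochs$data[keep, ch_idx[j], sel, drop = FALSE][, 1, , drop = FALSE],
                       dims = 1)
      dim(vals) <- NULL
      i <- i + 1
      rows[[i]] <- data.frame(epochs$events[keep, , drop = FALSE],
                              electrode = electrodes[j], window = w,
                              value = vals, feature_kind = "erp_mean",
                              row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Complex Morlet wavelet
#'
#' Gaussian-envelope complex exponential with `sigma_t = n_cycles / (2 pi f)`,
#' L2-normalized. The support is +/- 3 `sigma_t`, truncated symmetrically to
#' the signal length (and renormalized) when the signal covers at least
#' +/- 1 `sigma_t`; shorter signals raise an error.
#'
#' @param freq Center frequency (Hz).
#' @param sfreq Sampling rate (Hz).
#' @param n_cycles Number of cycles (default 7).
#' @param max_samples Optional cap on the wavelet length in samples.
#' @return Complex vector of odd length.
#' @export
morlet_wavelet <- function(freq, sfreq, n_cycles = 7, max_samples = NULL) {
  sigma_t <- n_cycles / (2 * pi * freq)
  half <- floor(3 * sigma_t * sfreq)
  if (!is.null(max_samples)) {
    max_half <- (max_samples - 1) %/% 2
    if (max_half < floor(sigma_t * sfreq)) {
      stop_config("signal too short for a ", freq, " Hz wavelet (needs +/- 1 sigma_t)")
    }
    half <- min(half, max_half)
  }
  t <- seq(-half, half) / sfreq
  w <- exp(2i * pi * freq * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

#' Single-trial Morlet wavelet power
#'
#' Convolves each epoch and channel with 7-cycle complex Morlet wavelets and
#' returns squared magnitudes. Convolution is FFT-based linear convolution
#' with zero padding, cropped to the epoch ("same" alignment). Edge samples
#' within half a wavelet length of either end are flagged as contaminated in
#' the `edge_valid` attribute (frequencies x samples logical matrix).
#'
#' @param epochs An `epoch_set`.
#' @param freqs Frequency grid in Hz (default `1:30`).
#' @param n_cycles Wavelet cycles (default 7).
#' @return Array `[epochs x channels x freqs x samples]` of power, with
#'   attribute `edge_valid`; dimnames carry channels and frequencies.
#' @export
morlet_power <- function(epochs, freqs = 1:30, n_cycles = 7) {
  n_s <- length(epochs$times)
  wl <- lapply(freqs, morlet_wavelet, sfreq = epochs$sfreq, n_cycles = n_cycles,
               max_samples = n_s)
  n_fft <- stats::nextn(n_s + max(lengths(wl)) - 1, 2)
  wl_fft <- lapply(wl, function(w) stats::fft(c(w, rep(0, n_fft - length(w)))))
  halves <- vapply(wl, function(w) (length(w) - 1L) %/% 2L, integer(1))
  n_e <- n_epochs(epochs)
  n_c <- length(epochs$channels)
  pow <- array(NA_real_, dim = c(n_e, n_c, length(freqs), n_s),
               dimnames = list(NULL, epochs$channels, freqs, NULL))
  for (e in seq_len(n_e)) {
    for (ch in seq_len(n_c)) {
      xf <- stats::fft(c(epochs$data[e, ch, ], rep(0, n_fft - n_s)))
      for (fi in seq_along(freqs)) {
        conv <- stats::fft(xf * wl_fft[[fi]], inverse = TRUE) / n_fft
        # "same" alignment: drop the wavelet half-length lead-in
        pow[e, ch, fi, ] <- Mod(conv[halves[fi] + seq_len(n_s)])^2
      }
    }
  }
  edge_valid <- matrix(TRUE, length(freqs), n_s)
  for (fi in seq_along(freqs)) {
    h <- halves[fi]
    if (h > 0) edge_valid[fi, c(seq_len(min(h, n_s)),
                                seq.int(max(1L, n_s - h + 1L), n_s))] <- FALSE
  }
  attr(pow, "edge_valid") <- edge_valid
  attr(pow, "times") <- epochs$times
  pow
}

#' Baseline-ratio normalization of wavelet power
#'
#' Divides every power value by the mean power over the baseline window for
#' the same epoch, channel, and frequency.
#'
#' @param power Output of [morlet_power()].
#' @param baseline Length-2 window in seconds (default `c(-0.4, -0.1)`).
#' @return Array of the same shape, strictly positive where power is positive.
#' @export
baseline_ratio <- function(power, baseline = c(-0.4, -0.1)) {
  times <- attr(power, "times")
  sel <- times >= baseline[1] & times < baseline[2]
  if (!any(sel)) stop_config("baseline window has no samples")
  base <- apply(power[, , , sel, drop = FALSE], c(1, 2, 3), mean)
  if (any(base == 0)) stop_config("zero baseline power (degenerate input)")
  out <- power / as.vector(base)
  attr(out, "edge_valid") <- attr(power, "edge_valid")
  attr(out, "times") <- times
  out
}

#' Band x window means of normalized power
#'
#' Averages baseline-normalized power over the frequencies of each band
#' (grid points; closed upper bound, open lower bound except for the lowest
#' edge) and the samples of each half-open time window.
#'
#' @param npower Output of [baseline_ratio()].
#' @param epochs The `epoch_set` the power was computed from (for events and
#'   rejection flags).
#' @param bands Named list of band edges in Hz (default [freq_bands()]).
#' @param windows Named list of windows in ms (default [tf_windows_ms()]).
#' @param electrodes Channel labels to analyze.
#' @return Long data frame: event keys, `electrode`, `band`, `window`,
#'   `value`, `feature_kind = "band_power_ratio"`.
#' @export
band_window_means <- function(npower, epochs, bands = freq_bands(),
                              windows = tf_windows_ms(),
                              electrodes = c("Fz", "Cz", "Pz")) {
  times <- attr(npower, "times")
  freqs <- as.numeric(dimnames(npower)[[3]])
  ch_idx <- channel_index(epochs, electrodes)
  keep <- which(!epochs$rejected)
  rows <- list()
  for (b in names(bands)) {
    fsel <- band_mask(freqs, b, bands)
    if (!any(fsel)) next
    for (w in names(windows)) {
      tsel <- times >= windows[[w]][1] / 1000 & times < windows[[w]][2] / 1000
      for (j in seq_along(electrodes)) {
        block <- npower[keep, ch_idx[j], fsel, tsel, drop = FALSE]
        vals <- apply(block, 1, mean)
        rows[[length(rows) + 1]] <-
          data.frame(epochs$events[keep, , drop = FALSE],
                     electrode = electrodes[j], band = b, window = w,
                     value = vals, feature_kind = "band_power_ratio",
                     row.names = NULL)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Band-power features computed epoch by epoch
#'
#' Memory-lean pipeline equivalent of [morlet_power()] +
#' [baseline_ratio()] + [band_window_means()]: the full time-frequency array
#' is never held for more than one epoch.
#'
#' @inheritParams band_window_means
#' @inheritParams morlet_power
#' @param baseline Baseline window in seconds.
#' @export
tf_band_features <- function(epochs, freqs = 1:30, n_cycles = 7,
                             baseline = c(-0.4, -0.1), bands = freq_bands(),
                             windows = tf_windows_ms(),
                             electrodes = c("Fz", "Cz", "Pz")) {
  keep <- which(!epochs$rejected)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    one <- subset_epochs(epochs, keep[i])
    p <- morlet_power(one, freqs, n_cycles)
    np <- baseline_ratio(p, baseline)
    out[[i]] <- band_window_means(np, one, bands, windows, electrodes)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hook for external preprocessing of real recordings
#'
#' Synthetic epochs are generated referenced and artifact-free, so this is an
#' identity pass; adapters for real recordings (re-referencing, component
#' based artifact removal) can replace it.
#'
#' @param epochs An `epoch_set`.
#' @export
preprocess_external <- function(epochs) epochs
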