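# Epoch averaging into one-period SSVEP waveforms, and the spectral
# descriptors (peak-to-peak amplitude, pre-flicker alpha spectrum,
# individual alpha frequency).

#' Average kept segments into an SSVEP waveform
#'
#' Pointwise mean over the kept segments of one channel; averaging N epochs
#' of one flicker period acts as a comb filter, retaining only the flicker
#' frequency and its harmonics. With `max_duration` only segments whose
#' trigger occurred within the first `max_duration` seconds of flicker are
#' used (e.g. 0.3 s of 10 Hz flicker uses 3 segments).
#'
#' @param seg A [segment_recording()] result (after optional
#'   [reject_artifacts()]).
#' @param channel Channel name, e.g. `"O1"`.
#' @param max_duration Seconds of flicker data to use, counted from flicker
#'   onset; `NULL` uses everything.
#' @return An `ssvep` object: `waveform` (microvolts, one flicker period),
#'   `channel`, `n_segments_used`, `duration_used`, `filter_tag`, `meta`.
#' @export
average_segments <- function(seg, channel, max_duration = NULL) {
  stopifnot(inherits(seg, "segment_set"))
  if (!channel %in% dimnames(seg$epochs)[[2]]) {
    stop("channel not present: ", channel, call. = FALSE)
  }
  use <- seg$keep
  if (!is.null(max_duration)) {
    use <- use & seg$trigger_times < max_duration
  }
  if (!any(use)) stop("no kept segments within `max_duration`", call. = FALSE)
  wf <- colMeans(matrix(seg$epochs[use, channel, ], ncol = seg$period_samples))
  structure(
    list(
      waveform = wf,
      channel = channel,
      n_segments_used = sum(use),
      duration_used = max_duration %||% (max(seg$trigger_times) + seg$period_samples / seg$fs),
      fs = seg$fs,
      filter_tag = seg$filter_tag,
      meta = seg$meta
    ),
    class = "ssvep"
  )
}

#' @export
print.ssvep <- function(x, ...) {
  cat(sprintf(
    "<ssvep> channel %s, %d samples (%.0f ms), averaged over %d segments\n",
    x$channel, length(x$waveform), 1000 * length(x$waveform) / x$fs,
    x$n_segments_used
  ))
  invisible(x)
}

#' Peak-to-peak amplitude of a waveform
#'
#' The conventional SSVEP magnitude measure: `max(waveform) - min(waveform)`.
#'
#' @param x An `ssvep` or a numeric vector.
#' @return Peak-to-peak amplitude in the waveform's units.
#' @export
peak_to_peak <- function(x) {
  v <- if (inherits(x, "ssvep")) x$waveform else as.numeric(x)
  max(v) - min(v)
}

# One-sided amplitude spectrum of a mean-subtracted, Hann-windowed signal.
# Convention: 2 * |FFT| / N; any fixed convention works since the analysis
# only compares amplitudes.
hann_amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sp <- stats::fft(x * w)
  n_pos <- floor(n / 2) + 1
  list(
    freqs = (seq_len(n_pos) - 1) * fs / n,
    amps = 2 * Mod(sp[seq_len(n_pos)]) / n
  )
}

#' Alpha spectrum of the pre-flicker baseline
#'
#' Extracts the 4 s window starting 1 s after the trial start (skipping the
#' button-press movement artifact), subtracts its mean, applies a Hann
#' window and an FFT. A 4 s window gives a 0.25 Hz frequency resolution. The
#' alpha peak is the maximum amplitude between 8 and 14 Hz.
#'
#' @param rec An [recording()]; needs at least 5 s before the first trigger
#'   (or at least 5 s of data if there are no triggers).
#' @param channel Channel name.
#' @param band Alpha search band in Hz.
#' @return An `alpha_spectrum`: `freqs` (0.25 Hz grid), `amps`, `peak_freq`,
#'   `peak_amp`.
#' @export
baseline_alpha <- function(rec, channel, band = c(8, 14)) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  limit <- if (length(rec$triggers) > 0) rec$triggers[1] - 1 else n_samples(rec)
  if (limit < 5 * fs) {
    stop("pre-flicker period shorter than 5 s", call. = FALSE)
  }
  x <- rec$data[(fs + 1):(5 * fs), channel]
  sp <- hann_amplitude_spectrum(x, fs)
  in_band <- sp$freqs >= band[1] & sp$freqs <= band[2]
  peak_i <- which(in_band)[which.max(sp$amps[in_band])] # ties: lowest frequency
  structure(
    list(
      freqs = sp$freqs, amps = sp$amps,
      peak_freq = sp$freqs[peak_i], peak_amp = sp$amps[peak_i],
      channel = channel, meta = rec$meta
    ),
    class = "alpha_spectrum"
  )
}

#' Estimate the individual alpha frequency from an eyes-closed recording
#'
#' Cuts the recording into non-overlapping 4 s windows (0.25 Hz resolution),
#' computes Hann-windowed amplitude spectra per window and electrode,
#' averages all spectra, and returns the frequency of the maximum between 8
#' and 14 Hz (ties broken towards the lower frequency).
#'
#' @param rec An eyes-closed [recording()] of at least 4 s.
#' @param electrodes Electrodes averaged over (the occipital/parietal set by
#'   default).
#' @param band Alpha search band in Hz.
#' @param window Window length in seconds (4 s -> 0.25 Hz resolution).
#' @return The individual alpha frequency in Hz, on the 0.25 Hz grid. Always
#'   inside `band`, even for a flat spectrum (degenerate inputs yield the
#'   argmax of noise).
#' @export
estimate_iaf <- function(rec, electrodes = c("O1", "O2", "P3", "P4", "P7", "P8"),
                         band = c(8, 14), window = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing_el <- setdiff(electrodes, colnames(rec$data))
  if (length(missing_el) > 0) {
    stop("electrode(s) missing from recording: ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  fs <- rec$fs
  wlen <- round(window * fs)
  n_win <- floor(n_samples(rec) / wlen)
  if (n_win < 1) stop("recording shorter than one analysis window", call. = FALSE)
  acc <- NULL
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    for (el in electrodes) {
      sp <- hann_amplitude_spectrum(rec$data[idx, el], fs)
      acc <- if (is.null(acc)) sp$amps else acc + sp$amps
    }
  }
  freqs <- (seq_along(acc) - 1) / window
  in_band <- freqs >= band[1] & freqs <= band[2]
  freqs[in_band][which.max(acc[in_band])]
}
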