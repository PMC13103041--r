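# Trigger-locked segmentation, peak-to-peak artifact rejection, and the
# zero-phase filters applied to the continuous data before segmentation.

#' Cut one-flicker-period segments at the trigger events
#'
#' One segment per trigger, starting at the trigger sample and lasting
#' `round(fs / flicker_freq)` samples (e.g. 100 samples for 10 Hz flicker at
#' 1000 Hz: a 100 ms epoch). Triggers whose segment would overrun the
#' recording are dropped and counted. After a filter has been applied to the
#' recording, triggers within the first and last second are additionally
#' excluded to avoid filter edge transients.
#'
#' @param rec An [recording()].
#' @param flicker_freq Flicker frequency in Hz; defaults to the recording's
#'   metadata.
#' @return A `segment_set`: array `epochs` (segments x channels x samples),
#'   `keep` mask, per-segment `reject_reason` (`none`/`eog`/`motion`),
#'   `trigger_times` in seconds relative to flicker onset, `period_samples`,
#'   and counts of dropped triggers.
#' @export
segment_recording <- function(rec, flicker_freq = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  f <- flicker_freq %||% rec$meta$flicker_freq
  if (is.null(f)) stop("`flicker_freq` not given and absent from metadata", call. = FALSE)
  if (length(rec$triggers) == 0) stop("no flicker events in recording", call. = FALSE)
  p <- round(rec$fs / f)
  n <- n_samples(rec)
  edge <- round(rec$edge_exclude * rec$fs)
  ok <- rec$triggers > edge & (rec$triggers + p - 1) <= (n - edge)
  n_dropped <- sum(!ok)
  trig <- rec$triggers[ok]
  if (length(trig) == 0) stop("no usable flicker events after edge handling", call. = FALSE)

  nc <- ncol(rec$data)
  epochs <- array(NA_real_, dim = c(length(trig), nc, p),
                  dimnames = list(NULL, colnames(rec$data), NULL))
  offs <- 0:(p - 1)
  for (s in seq_along(trig)) {
    epochs[s, , ] <- t(rec$data[trig[s] + offs, , drop = FALSE])
  }

  structure(
    list(
      epochs = epochs,
      keep = rep(TRUE, length(trig)),
      reject_reason = rep("none", length(trig)),
      period_samples = p,
      trigger_times = (trig - rec$triggers[1]) / rec$fs,
      fs = rec$fs,
      roles = rec$roles,
      n_dropped = n_dropped,
      filter_tag = rec$filter_tag,
      meta = rec$meta
    ),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf(
    "<segment_set> %d segments x %d channels x %d samples (%d kept, %d dropped at edges)\n",
    dim(x$epochs)[1], dim(x$epochs)[2], x$period_samples, sum(x$keep), x$n_dropped
  ))
  invisible(x)
}

#' Reject segments contaminated by eye blinks or head motion
#'
#' A segment is rejected if its within-segment peak-to-peak amplitude exceeds
#' `eog_threshold` (default 100 microvolts) on either EOG channel, or
#' `motion_threshold` (default 30 mg) on any accelerometer axis. EEG samples
#' are never altered; only the keep mask and the per-segment reason change.
#' EOG excursions take precedence in the recorded reason when both apply.
#'
#' @param seg A `segment_set`.
#' @param eog_threshold EOG peak-to-peak rejection threshold in microvolts.
#' @param motion_threshold Accelerometer peak-to-peak threshold in mg.
#' @param allow_missing If `TRUE`, silently skip a criterion whose channels
#'   are absent (explicit no-rejection pass-through); otherwise missing
#'   EOG/accelerometer channels are an error.
#' @return The `segment_set` with updated `keep` and `reject_reason`.
#' @export
reject_artifacts <- function(seg, eog_threshold = 100, motion_threshold = 30,
                             allow_missing = FALSE) {
  stopifnot(inherits(seg, "segment_set"))
  eog <- names(seg$roles)[seg$roles %in% c("EOG_v", "EOG_h")]
  acc <- names(seg$roles)[seg$roles %in% c("ACC_x", "ACC_y", "ACC_z")]
  if (!allow_missing && (length(eog) == 0 || length(acc) == 0)) {
    stop("EOG and accelerometer channels are required for artifact rejection; ",
         "use `allow_missing = TRUE` to skip", call. = FALSE)
  }
  ptp_by_seg <- function(chs) {
    if (length(chs) == 0) return(rep(0, dim(seg$epochs)[1]))
    sub <- seg$epochs[, chs, , drop = FALSE]
    apply(sub, 1, function(m) max(apply(matrix(m, nrow = length(chs)), 1,
                                        function(v) max(v) - min(v))))
  }
  eog_hit <- ptp_by_seg(eog) > eog_threshold
  acc_hit <- ptp_by_seg(acc) > motion_threshold
  seg$reject_reason[acc_hit] <- "motion"
  seg$reject_reason[eog_hit] <- "eog"
  seg$keep <- !(eog_hit | acc_hit)
  seg
}

apply_filtfilt <- function(rec, filt, tag, roles = c("EEG", "EOG_v", "EOG_h")) {
  chs <- channels_with_role(rec, roles)
  for (ch in chs) {
    rec$data[, ch] <- signal::filtfilt(filt, rec$data[, ch])
  }
  rec$filter_tag <- tag
  rec$edge_exclude <- max(rec$edge_exclude, 1)
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' A 4th-order Butterworth band-pass at `center +/- half_width` Hz applied
#' forwards and backwards (zero-phase) to the continuous EEG and EOG
#' channels; accelerometer channels are untouched. The default +/- 1 Hz band
#' isolates a single flicker harmonic.
#'
#' @param rec An [recording()].
#' @param center Band centre frequency in Hz.
#' @param half_width Half bandwidth in Hz (band is `center +/- half_width`).
#' @param order Butterworth design order (default 4).
#' @return The filtered recording; its `filter_tag` records the band and
#'   subsequent segmentation excludes 1 s at each edge.
#' @export
bandpass_filter <- function(rec, center, half_width = 1, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  lo <- center - half_width
  hi <- center + half_width
  if (lo <= 0) stop("lower band edge must be positive", call. = FALSE)
  if (hi >= rec$fs / 2) {
    stop(sprintf("upper band edge %g Hz is at or above Nyquist (%g Hz)",
                 hi, rec$fs / 2), call. = FALSE)
  }
  bt <- signal::butter(order, c(lo, hi) / (rec$fs / 2), type = "pass")
  rec <- apply_filtfilt(rec, bt, sprintf("bandpass %g+/-%g Hz", center, half_width))
  rec$meta$filter_center <- center
  rec$meta$filter_half_width <- half_width
  rec
}

#' Zero-phase 50 Hz notch filter
#'
#' Second-order IIR notch (constrained biquad) with quality factor 30,
#' applied forwards and backwards to the EEG and EOG channels; used to check
#' that mains noise does not contribute to decoding.
#'
#' @param rec An [recording()].
#' @param freq Notch frequency in Hz (default 50).
#' @param q Quality factor (default 30; -3 dB bandwidth = freq / q).
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, freq = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * freq) stop("sampling rate too low for this notch", call. = FALSE)
  w0 <- 2 * pi * freq / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filt <- signal::Arma(b = b / a[1], a = a / a[1])
  apply_filtfilt(rec, filt, sprintf("notch %g Hz Q=%g", freq, q))
}
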