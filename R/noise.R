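# Background-activity model for the synthetic generator: 1/f broadband
# noise, a participant-specific alpha oscillator, eye-blink transients and
# head-motion bursts.

#' Background noise and artifact settings for synthetic EEG
#'
#' Population defaults for the alpha oscillator follow the reported
#' individual alpha frequency distribution (mean 10.275 Hz, SD 0.843 Hz,
#' range clamped to 8-14 Hz). Blink and motion amplitudes default to values
#' that exceed the artifact-rejection thresholds (100 microvolt EOG
#' peak-to-peak; 30 mg acceleration), so rejection logic is exercised on both
#' sides by scaling them.
#'
#' @param one_over_f_exponent Spectral exponent beta of the 1/f^beta
#'   broadband background (unitless).
#' @param broadband_rms RMS of the broadband background in microvolts.
#' @param alpha_freq Individual alpha frequency in Hz; must lie in `[8, 14]`.
#' @param alpha_rms RMS of the alpha oscillator in microvolts.
#' @param blink_rate Poisson rate of eye blinks in events/s.
#' @param blink_amp Peak amplitude of the blink transient on vertical EOG in
#'   microvolts.
#' @param motion_rate Poisson rate of head-motion bursts in events/s.
#' @param motion_amp Peak amplitude of motion bursts on the accelerometer in
#'   milli-g.
#' @param acc_noise_rms Accelerometer sensor noise RMS in milli-g.
#' @return A `noise_model` object.
#' @export
noise_model <- function(one_over_f_exponent = 1, broadband_rms = 10,
                        alpha_freq = 10.275, alpha_rms = 5,
                        blink_rate = 0.2, blink_amp = 250,
                        motion_rate = 0.05, motion_amp = 50,
                        acc_noise_rms = 1) {
  if (alpha_freq < 8 || alpha_freq > 14) {
    stop("`alpha_freq` must lie in [8, 14] Hz", call. = FALSE)
  }
  for (nm in c("broadband_rms", "alpha_rms", "blink_rate", "blink_amp",
               "motion_rate", "motion_amp", "acc_noise_rms")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      stop(sprintf("`%s` must be a non-negative number", nm), call. = FALSE)
    }
  }
  structure(
    list(
      one_over_f_exponent = one_over_f_exponent,
      broadband_rms = broadband_rms,
      alpha_freq = alpha_freq, alpha_rms = alpha_rms,
      blink_rate = blink_rate, blink_amp = blink_amp,
      motion_rate = motion_rate, motion_amp = motion_amp,
      acc_noise_rms = acc_noise_rms
    ),
    class = "noise_model"
  )
}

#' Draw a participant-specific alpha frequency
#'
#' Normal draw with mean 10.275 Hz and SD 0.843 Hz, clamped to `[8, 14]` Hz.
#'
#' @param seed Integer seed.
#' @return Alpha frequency in Hz.
#' @export
draw_alpha_freq <- function(seed) {
  with_seed(seed, f <- stats::rnorm(1, 10.275, 0.843))
  min(14, max(8, f))
}

# 1/f^beta noise by spectral shaping of white Gaussian noise, scaled to a
# target RMS. Uses the caller's RNG stream.
pink_noise <- function(n, fs, exponent = 1, rms = 1) {
  if (rms == 0 || n == 0) {
    return(numeric(n))
  }
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  freqs <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- c(0, freqs[-1]^(-exponent / 2)) # kill DC
  shaped <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  shaped * rms / stats::sd(shaped)
}

# Narrow-band alpha oscillator: white noise band-passed +/-1 Hz around the
# individual alpha frequency, scaled to a target RMS. Uses the caller's RNG.
alpha_oscillation <- function(n, fs, freq, rms = 1) {
  if (rms == 0 || n == 0) {
    return(numeric(n))
  }
  bw <- signal::butter(2, c(freq - 1, freq + 1) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bw, stats::rnorm(n))
  x * rms / stats::sd(x)
}

#' Biphasic eye-blink template
#'
#' A smooth biphasic transient of 400 ms duration normalised to unit peak
#' amplitude; scaled by the configured blink amplitude when placed on the
#' EOG channels.
#'
#' @param fs Sampling rate in Hz.
#' @param duration Template duration in seconds.
#' @return Numeric vector of `round(duration * fs)` samples, peak |value| 1.
#' @export
blink_template <- function(fs, duration = 0.4) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / n
  w <- sin(2 * pi * t) * sin(pi * t)^2
  w / max(abs(w))
}

# Place Poisson events on a trace; returns the trace and the onset times (s).
# Uses the caller's RNG stream.
add_blinks <- function(n, fs, rate, amp) {
  out <- numeric(n)
  times <- numeric(0)
  if (rate > 0 && amp > 0) {
    dur <- n / fs
    k <- stats::rpois(1, rate * dur)
    if (k > 0) {
      times <- sort(stats::runif(k, 0, dur - 0.4))
      tmpl <- blink_template(fs) * amp
      for (tt in times) {
        i0 <- round(tt * fs) + 1
        idx <- i0:(i0 + length(tmpl) - 1)
        ok <- idx <= n
        out[idx[ok]] <- out[idx[ok]] + tmpl[ok]
      }
    }
  }
  list(trace = out, times = times)
}

# Head-motion bursts: 1-2 s smoothed random walks, normalised to a peak
# amplitude. Returns per-axis traces plus burst onset times.
add_motion <- function(n, fs, rate, amp, n_axes = 3) {
  out <- matrix(0, n, n_axes)
  times <- numeric(0)
  if (rate > 0 && amp > 0) {
    dur <- n / fs
    k <- stats::rpois(1, rate * dur)
    if (k > 0) {
      times <- sort(stats::runif(k, 0, max(dur - 2, 0.1)))
      for (tt in times) {
        blen <- round(stats::runif(1, 1, 2) * fs)
        i0 <- round(tt * fs) + 1
        idx <- i0:min(i0 + blen - 1, n)
        for (ax in seq_len(n_axes)) {
          walk <- cumsum(stats::rnorm(length(idx)))
          walk <- stats::filter(walk, rep(1 / round(fs * 0.05 + 1), round(fs * 0.05 + 1)),
                                sides = 2)
          walk[is.na(walk)] <- 0
          walk <- walk * sin(pi * seq_along(idx) / length(idx))^2 # taper to 0 at edges
          if (max(abs(walk)) > 0) walk <- walk * amp / max(abs(walk))
          out[idx, ax] <- out[idx, ax] + walk
        }
      }
    }
  }
  list(trace = out, times = times)
}
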