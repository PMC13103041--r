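# Ground-truth periodic waveform model for the synthetic generator.
#
# Each (participant, scene) pair owns an idiosyncratic SSVEP-like waveform
# built from the harmonics of the flicker frequency: amplitudes follow a
# decaying k^(-gamma) envelope times a per-harmonic lognormal factor, phases
# are uniform. This mirrors the empirical observation that scene information
# is spread over many flicker harmonics while power falls off with frequency.

#' Draw an idiosyncratic periodic waveform for one participant and scene
#'
#' The waveform is a sum of `n_harmonics` harmonics of the flicker frequency
#' with amplitudes `a_k = k^(-gamma) * lognormal` (in microvolts) and phases
#' uniform on `[0, 2*pi)`. The draw is a deterministic function of
#' `(participant_id, scene_id, seed)`, so the same identifiers always yield
#' the same ground-truth shape.
#'
#' @param participant_id,scene_id Identifiers (any scalar, coerced to
#'   character) that seed the idiosyncratic draw.
#' @param flicker_freq Flicker frequency in Hz.
#' @param n_harmonics Number of harmonics K (>= 1). The default 24 spans
#'   10-240 Hz at 10 Hz flicker, covering the range over which band-limited
#'   scene information is plausibly present.
#' @param seed Master seed.
#' @param gamma Harmonic amplitude decay exponent (default 1).
#' @param amp_sdlog Lognormal sdlog of the per-harmonic amplitude factor.
#' @param base_amp Overall scale in microvolts of the first harmonic envelope.
#' @param fs Sampling rate in Hz used only to refuse waveforms whose highest
#'   harmonic exceeds the Nyquist frequency.
#' @return A `waveform_model` object with fields `flicker_freq`,
#'   `harmonic_amps`, `harmonic_phases`, `participant_id`, `scene_id`.
#' @export
#' @examples
#' w <- draw_waveform("P01", "forest", flicker_freq = 10, n_harmonics = 4, seed = 1)
#' plot(waveform_period(w, fs = 1000), type = "l")
draw_waveform <- function(participant_id, scene_id, flicker_freq = 10,
                          n_harmonics = 24, seed = 1, gamma = 1,
                          amp_sdlog = 0.8, base_amp = 5, fs = 1000) {
  stopifnot_scalar_numeric(flicker_freq, "flicker_freq", positive = TRUE)
  if (n_harmonics < 1) stop("`n_harmonics` must be >= 1", call. = FALSE)
  if (n_harmonics * flicker_freq >= fs / 2) {
    stop(sprintf(
      "highest harmonic %g Hz is at or above Nyquist (%g Hz); reduce `n_harmonics`",
      n_harmonics * flicker_freq, fs / 2
    ), call. = FALSE)
  }
  k <- seq_len(n_harmonics)
  cs <- child_seed(seed, "waveform", participant_id, scene_id)
  with_seed(cs, {
    amps <- base_amp * k^(-gamma) * stats::rlnorm(n_harmonics, 0, amp_sdlog)
    phases <- stats::runif(n_harmonics, 0, 2 * pi)
  })
  structure(
    list(
      flicker_freq = flicker_freq,
      harmonic_amps = amps,
      harmonic_phases = phases,
      participant_id = as.character(participant_id),
      scene_id = as.character(scene_id),
      gamma = gamma,
      amp_sdlog = amp_sdlog,
      base_amp = base_amp
    ),
    class = "waveform_model"
  )
}

#' Evaluate a waveform model at arbitrary times
#'
#' @param wave A `waveform_model`.
#' @param t Times in seconds.
#' @return Microvolt values; exactly periodic with period `1/flicker_freq`.
#' @export
eval_waveform <- function(wave, t) {
  stopifnot(inherits(wave, "waveform_model"))
  k <- seq_along(wave$harmonic_amps)
  # t x K phase matrix; column-wise weighted sum
  ph <- outer(2 * pi * wave$flicker_freq * t, k) +
    rep(wave$harmonic_phases, each = length(t))
  as.vector(cos(ph) %*% wave$harmonic_amps)
}

#' Evaluate one flicker period of a waveform model on the sampling grid
#'
#' @param wave A `waveform_model`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector of length `round(fs / flicker_freq)`.
#' @export
waveform_period <- function(wave, fs = 1000) {
  p <- round(fs / wave$flicker_freq)
  eval_waveform(wave, (seq_len(p) - 1) / fs)
}

#' Session-to-session drift settings
#'
#' `stability` mixes the session-1 waveform with an independent redraw on the
#' complex harmonic coefficients; 1 keeps the waveform identical, 0 replaces
#' it. `amp_scale_jitter` is the sdlog of a single multiplicative amplitude
#' factor applied afterwards (shape-preserving gain change between days).
#'
#' @param stability Mixing weight in `[0, 1]`.
#' @param amp_scale_jitter Lognormal sdlog of the session gain factor (>= 0).
#' @return A `session_drift` object.
#' @export
session_drift <- function(stability = 0.9, amp_scale_jitter = 0.1) {
  if (stability < 0 || stability > 1) {
    stop("`stability` must lie in [0, 1]", call. = FALSE)
  }
  if (amp_scale_jitter < 0) stop("`amp_scale_jitter` must be >= 0", call. = FALSE)
  structure(list(stability = stability, amp_scale_jitter = amp_scale_jitter),
            class = "session_drift")
}

#' Drift a waveform between sessions
#'
#' Harmonic-wise on complex coefficients `c_k = a_k exp(i phi_k)`:
#' `c2 = s * c1 + sqrt(1 - s^2) * c_indep`, where `c_indep` is an independent
#' redraw from the same generative model, followed by a global multiplicative
#' amplitude jitter. For large K the expected Pearson correlation between the
#' drifted and original period waveforms is approximately `s`.
#'
#' @param wave A `waveform_model`.
#' @param drift A [session_drift()].
#' @param seed Seed for the redraw and jitter.
#' @return A drifted `waveform_model`.
#' @export
drift_waveform <- function(wave, drift, seed = 1) {
  stopifnot(inherits(wave, "waveform_model"), inherits(drift, "session_drift"))
  s <- drift$stability
  if (s == 1 && drift$amp_scale_jitter == 0) {
    return(wave)
  }
  k <- length(wave$harmonic_amps)
  cs <- child_seed(seed, "drift", wave$participant_id, wave$scene_id)
  # independent redraw from the same generative model as draw_waveform, so
  # the mixed coefficients keep the original marginal power structure
  gamma <- wave$gamma %||% 1
  amp_sdlog <- wave$amp_sdlog %||% 0.8
  base_amp <- wave$base_amp %||% 5
  with_seed(cs, {
    indep_amps <- base_amp * seq_len(k)^(-gamma) * stats::rlnorm(k, 0, amp_sdlog)
    indep_phases <- stats::runif(k, 0, 2 * pi)
    gain <- stats::rlnorm(1, 0, drift$amp_scale_jitter)
  })
  c1 <- wave$harmonic_amps * exp(1i * wave$harmonic_phases)
  ci <- indep_amps * exp(1i * indep_phases)
  c2 <- (s * c1 + sqrt(1 - s^2) * ci) * gain
  out <- wave
  out$harmonic_amps <- Mod(c2)
  out$harmonic_phases <- Arg(c2)
  out
}

#' @export
print.waveform_model <- function(x, ...) {
  cat(sprintf(
    "<waveform_model> participant=%s scene=%s flicker=%g Hz, K=%d harmonics\n",
    x$participant_id, x$scene_id, x$flicker_freq, length(x$harmonic_amps)
  ))
  invisible(x)
}
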