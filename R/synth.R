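# Synthetic flicker-evoked EEG generator.
#
# Emulates the recording model of the mobile flicker-glasses setup: six
# occipital/parietal EEG channels carrying a participant-and-scene specific
# periodic waveform locked to the flicker triggers, two EOG channels with an
# attenuated copy plus blink transients, and three accelerometer axes with
# motion bursts but no flicker-locked component.

default_eeg_gains <- c(O1 = 1, O2 = 1.05, P3 = 0.8, P4 = 0.8, P7 = 0.7, P8 = 0.7)

#' Synthesize one flicker trial
#'
#' Produces a continuous 11-channel recording: a baseline without flicker,
#' a flicker period with one trigger per cycle aligned to each darkening of
#' the glasses, and a closing baseline. The ground-truth periodic waveform is
#' added to the EEG channels with per-channel gain and to the EOG channels at
#' `eog_gain`; accelerometer channels carry no flicker-locked component, so
#' they decode at chance by construction.
#'
#' @param wave A [draw_waveform()] model.
#' @param noise A [noise_model()].
#' @param duration Flicker duration in seconds (>= one flicker period).
#' @param fs Sampling rate in Hz (study default 1000).
#' @param duty_cycle Fraction of each cycle the glasses are dark, in (0, 1).
#'   Recorded in the metadata; the evoked response is modeled directly as the
#'   harmonic waveform.
#' @param baseline_pre,baseline_post Flicker-free baseline durations in
#'   seconds (study protocol: 5 s each).
#' @param seed Seed for this trial's noise and artifacts.
#' @param eeg_gains Named per-channel gain of the flicker waveform on the six
#'   EEG channels.
#' @param eog_gain Gain of the flicker waveform on the EOG channels relative
#'   to the best EEG channel (default 0.4: EOG decodes above chance but worse
#'   than EEG).
#' @param meta Extra metadata fields merged into the recording's metadata.
#' @return An [recording()] with trigger indices and metadata including blink
#'   and motion event onset times (`blink_times`, `motion_times`, seconds).
#' @export
#' @examples
#' w <- draw_waveform("P01", "wall", flicker_freq = 10, n_harmonics = 6, seed = 1)
#' rec <- synthesize_trial(w, noise_model(), duration = 2, fs = 250,
#'                         baseline_pre = 1, baseline_post = 0.5, seed = 1)
#' length(rec$triggers) # 20 cycles
synthesize_trial <- function(wave, noise = noise_model(), duration = 30,
                             fs = 1000, duty_cycle = 0.5,
                             baseline_pre = 5, baseline_post = 5, seed = 1,
                             eeg_gains = default_eeg_gains, eog_gain = 0.4,
                             meta = list()) {
  stopifnot(inherits(wave, "waveform_model"), inherits(noise, "noise_model"))
  f <- wave$flicker_freq
  if (duty_cycle <= 0 || duty_cycle >= 1) {
    stop("`duty_cycle` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (duration < 1 / f) {
    stop("`duration` must cover at least one flicker period", call. = FALSE)
  }
  if (length(wave$harmonic_amps) * f >= fs / 2) {
    stop("waveform harmonics exceed Nyquist for this sampling rate", call. = FALSE)
  }

  n <- round((baseline_pre + duration + baseline_post) * fs)
  trig0 <- round(baseline_pre * fs) + 1L
  n_cycles <- floor(duration * f + 1e-9)
  triggers <- as.integer(trig0 + round((seq_len(n_cycles) - 1) * fs / f))

  flick_idx <- trig0:min(trig0 + round(duration * fs) - 1, n)
  flick <- numeric(n)
  flick[flick_idx] <- eval_waveform(wave, (flick_idx - trig0) / fs)

  ch_names <- c(names(eeg_gains), "EOGv", "EOGh", "ACCx", "ACCy", "ACCz")
  data <- matrix(0, n, length(ch_names), dimnames = list(NULL, ch_names))

  blink <- with_seed(child_seed(seed, "blink"),
                     add_blinks(n, fs, noise$blink_rate, noise$blink_amp))
  motion <- with_seed(child_seed(seed, "motion"),
                      add_motion(n, fs, noise$motion_rate, noise$motion_amp))

  for (j in seq_along(eeg_gains)) {
    ch <- names(eeg_gains)[j]
    bg <- with_seed(child_seed(seed, "bg", ch), {
      pink_noise(n, fs, noise$one_over_f_exponent, noise$broadband_rms) +
        alpha_oscillation(n, fs, noise$alpha_freq, noise$alpha_rms)
    })
    data[, ch] <- eeg_gains[j] * flick + bg + 0.1 * blink$trace
  }
  for (ch in c("EOGv", "EOGh")) {
    bg <- with_seed(child_seed(seed, "bg", ch),
                    pink_noise(n, fs, noise$one_over_f_exponent, noise$broadband_rms))
    bfrac <- if (ch == "EOGv") 1 else 0.3
    data[, ch] <- eog_gain * flick + bg + bfrac * blink$trace
  }
  for (ax in 1:3) {
    ch <- c("ACCx", "ACCy", "ACCz")[ax]
    sens <- with_seed(child_seed(seed, "acc", ch),
                      stats::rnorm(n, 0, noise$acc_noise_rms))
    data[, ch] <- motion$trace[, ax] + sens
  }

  meta <- utils::modifyList(
    list(
      flicker_freq = f, duty_cycle = duty_cycle,
      baseline_pre = baseline_pre, baseline_post = baseline_post,
      participant = wave$participant_id, scene = wave$scene_id,
      blink_times = blink$times, motion_times = motion$times,
      kind = "flicker"
    ),
    meta
  )
  recording(data, fs, triggers, meta = meta)
}

#' Synthesize an eyes-closed resting recording
#'
#' Alpha plus 1/f background on the EEG channels, no flicker and no triggers;
#' used to estimate the individual alpha frequency.
#'
#' @param noise A [noise_model()].
#' @param duration Duration in seconds (study protocol: 30 s).
#' @param fs Sampling rate in Hz.
#' @param seed Seed.
#' @param alpha_boost Multiplier on `alpha_rms` for the eyes-closed state
#'   (alpha is strongest with eyes closed).
#' @param meta Extra metadata fields.
#' @return An [recording()] with no triggers.
#' @export
synth_eyes_closed <- function(noise = noise_model(), duration = 30, fs = 1000,
                              seed = 1, alpha_boost = 2, meta = list()) {
  n <- round(duration * fs)
  ch_names <- c(names(default_eeg_gains), "EOGv", "EOGh", "ACCx", "ACCy", "ACCz")
  data <- matrix(0, n, length(ch_names), dimnames = list(NULL, ch_names))
  for (ch in c(names(default_eeg_gains), "EOGv", "EOGh")) {
    has_alpha <- ch %in% names(default_eeg_gains)
    data[, ch] <- with_seed(child_seed(seed, "ec", ch), {
      pink_noise(n, fs, noise$one_over_f_exponent, noise$broadband_rms) +
        if (has_alpha) {
          alpha_oscillation(n, fs, noise$alpha_freq, alpha_boost * noise$alpha_rms)
        } else {
          0
        }
    })
  }
  for (ch in c("ACCx", "ACCy", "ACCz")) {
    data[, ch] <- with_seed(child_seed(seed, "ec", ch),
                            stats::rnorm(n, 0, noise$acc_noise_rms))
  }
  meta <- utils::modifyList(list(kind = "eyes_closed"), meta)
  recording(data, fs, triggers = integer(), meta = meta)
}

#' Generate a full factorial synthetic study
#'
#' Builds the study design of the flicker experiments: every participant sees
#' every scene in every session, `trials_per_scene` times. Within a session
#' all trials of a scene share one ground-truth waveform; between sessions
#' the waveform is passed through [drift_waveform()]. One eyes-closed
#' recording per participant and session is added for alpha-frequency
#' estimation. Identical `(design, master_seed)` inputs give a bit-identical
#' dataset.
#'
#' @param n_participants,n_scenes,n_sessions,trials_per_scene Design counts
#'   (all >= 1). The first experiment used 20 participants, 6 scenes, 2
#'   sessions and 2 trials per scene.
#' @param flicker_freq Flicker frequency in Hz.
#' @param duration Flicker duration per trial in seconds.
#' @param fs Sampling rate in Hz.
#' @param duty_cycle Flicker duty cycle.
#' @param baseline_pre,baseline_post Baseline durations in seconds.
#' @param n_harmonics Harmonics per ground-truth waveform.
#' @param noise A [noise_model()] template; each participant's `alpha_freq`
#'   is redrawn from the population distribution via [draw_alpha_freq()].
#' @param drift A [session_drift()] applied between consecutive sessions.
#' @param eyes_closed_duration Eyes-closed recording length in seconds.
#' @param master_seed Single master seed; all child streams derive from it.
#' @param snr_scale Multiplier applied to all ground-truth waveform
#'   amplitudes; 0 removes the flicker-locked signal entirely.
#' @return An `ssvep_study`: list with `recordings` (list of
#'   [recording()]s), `metadata` (tibble keyed by participant, session,
#'   scene, trial, with `idx` into `recordings`), `waveforms` (ground truth,
#'   `waveforms[[participant]][[scene]][[session]]`), `noise` (per
#'   participant) and `config`.
#' @export
make_study <- function(n_participants = 20, n_scenes = 6, n_sessions = 2,
                       trials_per_scene = 2, flicker_freq = 10, duration = 30,
                       fs = 1000, duty_cycle = 0.5,
                       baseline_pre = 5, baseline_post = 5,
                       n_harmonics = 24, noise = noise_model(),
                       drift = session_drift(), eyes_closed_duration = 30,
                       master_seed = 1, snr_scale = 1) {
  stopifnot(n_participants >= 1, n_scenes >= 1, n_sessions >= 1,
            trials_per_scene >= 1)
  participants <- sprintf("P%02d", seq_len(n_participants))
  scenes <- sprintf("scene%d", seq_len(n_scenes))

  recordings <- list()
  rows <- list()
  waveforms <- list()
  noises <- list()
  idx <- 0L

  for (p in participants) {
    pn <- noise
    pn$alpha_freq <- draw_alpha_freq(child_seed(master_seed, "iaf", p))
    noises[[p]] <- pn
    waveforms[[p]] <- list()
    for (sc in scenes) {
      w <- draw_waveform(p, sc, flicker_freq, n_harmonics, seed = master_seed,
                         fs = fs)
      w$harmonic_amps <- w$harmonic_amps * snr_scale
      waveforms[[p]][[sc]] <- list(w)
      if (n_sessions > 1) {
        for (se in 2:n_sessions) {
          prev <- waveforms[[p]][[sc]][[se - 1]]
          waveforms[[p]][[sc]][[se]] <-
            drift_waveform(prev, drift, seed = child_seed(master_seed, "sess", p, sc, se))
        }
      }
    }
    for (se in seq_len(n_sessions)) {
      for (sc in scenes) {
        for (tr in seq_len(trials_per_scene)) {
          idx <- idx + 1L
          rec <- synthesize_trial(
            waveforms[[p]][[sc]][[se]], pn, duration = duration, fs = fs,
            duty_cycle = duty_cycle, baseline_pre = baseline_pre,
            baseline_post = baseline_post,
            seed = child_seed(master_seed, "trial", p, sc, se, tr),
            meta = list(participant = p, session = se, scene = sc, trial = tr)
          )
          recordings[[idx]] <- rec
          rows[[idx]] <- tibble::tibble(
            idx = idx, participant = p, session = se, scene = sc, trial = tr,
            flicker_freq = flicker_freq, kind = "flicker"
          )
        }
      }
      idx <- idx + 1L
      recordings[[idx]] <- synth_eyes_closed(
        pn, duration = eyes_closed_duration, fs = fs,
        seed = child_seed(master_seed, "eyesclosed", p, se),
        meta = list(participant = p, session = se)
      )
      rows[[idx]] <- tibble::tibble(
        idx = idx, participant = p, session = se, scene = NA_character_,
        trial = NA_integer_, flicker_freq = NA_real_, kind = "eyes_closed"
      )
    }
  }

  structure(
    list(
      recordings = recordings,
      metadata = do.call(rbind, rows),
      waveforms = waveforms,
      noise = noises,
      config = list(
        n_participants = n_participants, n_scenes = n_scenes,
        n_sessions = n_sessions, trials_per_scene = trials_per_scene,
        flicker_freq = flicker_freq, duration = duration, fs = fs,
        duty_cycle = duty_cycle, baseline_pre = baseline_pre,
        baseline_post = baseline_post, n_harmonics = n_harmonics,
        drift = drift, master_seed = master_seed, snr_scale = snr_scale
      )
    ),
    class = "ssvep_study"
  )
}

#' @export
print.ssvep_study <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<ssvep_study> %d participants x %d scenes x %d sessions x %d trials @ %g Hz flicker (%d recordings)\n",
    cfg$n_participants, cfg$n_scenes, cfg$n_sessions, cfg$trials_per_scene,
    cfg$flicker_freq, length(x$recordings)
  ))
  invisible(x)
}
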