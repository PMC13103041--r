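# Shared fixtures: all synthetic, built in code at test time.

# Noise settings that switch off every stochastic component, so the epoch
# average must reproduce the ground-truth waveform exactly.
quiet_noise <- function(...) {
  args <- utils::modifyList(
    list(broadband_rms = 0, alpha_rms = 0, blink_rate = 0,
         motion_rate = 0, acc_noise_rms = 0),
    list(...)
  )
  do.call(noise_model, args)
}

# Small factorial study for pipeline tests; defaults keep runtime low while
# preserving the study structure (two sessions, two trials per scene).
small_study <- function(n_participants = 2, n_scenes = 3, n_sessions = 2,
                        trials_per_scene = 2, flicker_freq = 10,
                        duration = 3, fs = 250, n_harmonics = 6,
                        baseline_pre = 1, baseline_post = 0.5,
                        noise = quiet_noise(), drift = session_drift(),
                        master_seed = 1, ...) {
  make_study(
    n_participants = n_participants, n_scenes = n_scenes,
    n_sessions = n_sessions, trials_per_scene = trials_per_scene,
    flicker_freq = flicker_freq, duration = duration, fs = fs,
    n_harmonics = n_harmonics, baseline_pre = baseline_pre,
    baseline_post = baseline_post, noise = noise, drift = drift,
    master_seed = master_seed, ...
  )
}

# samples x conditions matrix of white-noise "waveforms" (structureless
# input for null-calibration tests)
rand_waveform_matrix <- function(n_samples, conditions) {
  matrix(rnorm(n_samples * length(conditions)), n_samples,
         dimnames = list(NULL, conditions))
}

# Hand-built one-channel segment set, for averaging tests that need exact
# control over the epochs.
manual_segment_set <- function(epochs_2d, fs = 1000, channel = "O1",
                               flicker_freq = 10) {
  n_seg <- nrow(epochs_2d)
  p <- ncol(epochs_2d)
  ep <- array(NA_real_, dim = c(n_seg, 1, p),
              dimnames = list(NULL, channel, NULL))
  ep[, 1, ] <- epochs_2d
  structure(
    list(
      epochs = ep,
      keep = rep(TRUE, n_seg),
      reject_reason = rep("none", n_seg),
      period_samples = p,
      trigger_times = (seq_len(n_seg) - 1) * p / fs,
      fs = fs,
      roles = c(O1 = "EEG"),
      n_dropped = 0L,
      filter_tag = "none",
      meta = list(flicker_freq = flicker_freq)
    ),
    class = "segment_set"
  )
}

# One-channel recording on an EEG channel name, for filter/spectral tests.
single_channel_recording <- function(x, fs, channel = "O1",
                                     triggers = integer(), meta = list()) {
  recording(matrix(x, ncol = 1, dimnames = list(NULL, channel)), fs,
            triggers = triggers, meta = meta)
}

# Least-squares amplitude of a sinusoid of known frequency in a short
# vector: exact for data that are pure sinusoids at that frequency.
fitted_amplitude <- function(x, freq, fs) {
  t <- (seq_along(x) - 1) / fs
  fit <- lm(x ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t))
  sqrt(sum(coef(fit)[2:3]^2))
}

# Single-session study assembled from explicitly constructed waveform models
# (waves[[participant]][[scene]]), for tests that need control over which
# harmonics differ between scenes.
build_study_from_waves <- function(waves,
                                   noise = noise_model(broadband_rms = 3,
                                                       alpha_rms = 0,
                                                       blink_rate = 0,
                                                       motion_rate = 0),
                                   trials_per_scene = 2, duration = 3,
                                   fs = 500, baseline_pre = 1,
                                   baseline_post = 0.5, master_seed = 1) {
  participants <- names(waves)
  scenes <- names(waves[[1]])
  recordings <- list()
  rows <- list()
  idx <- 0L
  for (p in participants) {
    for (sc in scenes) {
      for (tr in seq_len(trials_per_scene)) {
        idx <- idx + 1L
        recordings[[idx]] <- synthesize_trial(
          waves[[p]][[sc]], noise, duration = duration, fs = fs,
          baseline_pre = baseline_pre, baseline_post = baseline_post,
          seed = child_seed(master_seed, "trial", p, sc, tr),
          meta = list(participant = p, session = 1, scene = sc, trial = tr)
        )
        rows[[idx]] <- tibble::tibble(
          idx = idx, participant = p, session = 1L, scene = sc, trial = tr,
          flicker_freq = waves[[1]][[1]]$flicker_freq, kind = "flicker"
        )
      }
    }
  }
  structure(
    list(
      recordings = recordings,
      metadata = do.call(rbind, rows),
      waveforms = lapply(waves, function(ws) lapply(ws, list)),
      noise = stats::setNames(rep(list(noise), length(participants)), participants),
      config = list(
        n_participants = length(participants), n_scenes = length(scenes),
        n_sessions = 1L, trials_per_scene = trials_per_scene,
        flicker_freq = waves[[1]][[1]]$flicker_freq, duration = duration,
        fs = fs, baseline_pre = baseline_pre, baseline_post = baseline_post,
        master_seed = master_seed
      )
    ),
    class = "ssvep_study"
  )
}

# A waveform model whose harmonic coefficients are set explicitly.
explicit_wave <- function(amps, phases, flicker_freq = 10, p = "P01", sc = "s1") {
  w <- draw_waveform(p, sc, flicker_freq = flicker_freq,
                     n_harmonics = length(amps), seed = 1, fs = 1e6)
  w$harmonic_amps <- amps
  w$harmonic_phases <- phases
  w
}
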