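# End-to-end orchestration: validated study configuration plus the two
# experiment pipelines, each producing a bundle of tidy result tables.

#' Study configuration
#'
#' Collects the design counts, flicker protocol, generator settings and
#' analysis settings in one validated list that round-trips losslessly
#' through YAML. Defaults follow the first experiment's protocol: 20
#' participants, 6 scenes, 2 sessions at least a day apart, two 30 s trials
#' per scene at 10 Hz flicker (50% duty cycle), 5 s baselines, 1000 Hz
#' sampling.
#'
#' @param n_participants,n_scenes,n_sessions,trials_per_scene Design counts.
#' @param flicker_freq Flicker frequency in Hz.
#' @param duration Flicker duration per trial in seconds.
#' @param fs Sampling rate in Hz.
#' @param duty_cycle Flicker duty cycle in (0, 1).
#' @param baseline_pre,baseline_post Baseline durations in seconds.
#' @param n_harmonics Ground-truth waveform harmonics.
#' @param noise Generator noise settings, a [noise_model()] or plain list of
#'   its fields.
#' @param drift Session drift, a [session_drift()] or list of its fields.
#' @param snr_scale Multiplier on ground-truth waveform amplitudes.
#' @param durations Duration-sweep grid in seconds.
#' @param band_centers Band-sweep centre frequencies in Hz.
#' @param n_reps_null Replicates for the simulated null.
#' @param n_reps_perm Replicates for permutation tests.
#' @param bonferroni_tests Number of Bonferroni-corrected tests (8 channels
#'   in the first experiment, 3 flicker frequencies in the second).
#' @param seed Master seed.
#' @return A validated `study_config` list.
#' @export
study_config <- function(n_participants = 20, n_scenes = 6, n_sessions = 2,
                         trials_per_scene = 2, flicker_freq = 10,
                         duration = 30, fs = 1000, duty_cycle = 0.5,
                         baseline_pre = 5, baseline_post = 5,
                         n_harmonics = 24, noise = noise_model(),
                         drift = session_drift(), snr_scale = 1,
                         durations = c(30, 25, 20, 15, 10, 5, 4, 3, 2, 1,
                                       seq(0.9, 0.1, by = -0.1)),
                         band_centers = seq(10, 240, by = 10),
                         n_reps_null = 100000, n_reps_perm = 100000,
                         bonferroni_tests = 8, seed = 1) {
  if (!inherits(noise, "noise_model")) noise <- do.call(noise_model, as.list(noise))
  if (!inherits(drift, "session_drift")) drift <- do.call(session_drift, as.list(drift))
  cfg <- list(
    n_participants = n_participants, n_scenes = n_scenes,
    n_sessions = n_sessions, trials_per_scene = trials_per_scene,
    flicker_freq = flicker_freq, duration = duration, fs = fs,
    duty_cycle = duty_cycle, baseline_pre = baseline_pre,
    baseline_post = baseline_post, n_harmonics = n_harmonics,
    noise = noise, drift = drift, snr_scale = snr_scale,
    durations = durations, band_centers = band_centers,
    n_reps_null = n_reps_null, n_reps_perm = n_reps_perm,
    bonferroni_tests = bonferroni_tests, seed = seed
  )
  stopifnot(cfg$n_participants >= 1, cfg$n_scenes >= 1,
            cfg$duty_cycle > 0, cfg$duty_cycle < 1,
            cfg$duration >= 1 / cfg$flicker_freq)
  structure(cfg, class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' @param cfg A [study_config()].
#' @param path YAML file path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a validated `study_config`.
#' @export
write_study_config <- function(cfg, path) {
  plain <- lapply(unclass(cfg), function(v) if (is.list(v)) unclass(v) else v)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  do.call(study_config, yaml::read_yaml(path))
}

study_from_config <- function(cfg, ...) {
  make_study(
    n_participants = cfg$n_participants, n_scenes = cfg$n_scenes,
    n_sessions = cfg$n_sessions, trials_per_scene = cfg$trials_per_scene,
    flicker_freq = cfg$flicker_freq, duration = cfg$duration, fs = cfg$fs,
    duty_cycle = cfg$duty_cycle, baseline_pre = cfg$baseline_pre,
    baseline_post = cfg$baseline_post, n_harmonics = cfg$n_harmonics,
    noise = cfg$noise, drift = cfg$drift, master_seed = cfg$seed,
    snr_scale = cfg$snr_scale, ...
  )
}

participant_means <- function(res) {
  agg <- stats::aggregate(accuracy ~ participant, as.data.frame(res), mean)
  stats::setNames(agg$accuracy, agg$participant)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables)) {
    data.table::fwrite(bundle$tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Run the first experiment's full analysis on a synthetic study
#'
#' Generates the study from `cfg` and produces every analysis stage:
#' within- and between-session correlation decoding per electrode,
#' peak-to-peak amplitude decoding, the within-vs-between and
#' correlation-vs-amplitude permutation tests, the data-duration sweep, the
#' harmonic band-pass sweep, alpha-power decoding, participant-identity
#' decoding, alpha-frequency estimates with the decoding-vs-IAF-distance
#' correlation, and the simulated null threshold.
#'
#' @param cfg A [study_config()].
#' @param out_dir Optional directory: every table is written as CSV plus a
#'   `manifest.yaml` recording the seed and design.
#' @return A result bundle: `study`, `tables` (named tibbles), `null`
#'   (the [simulate_null()] object) and `manifest`.
#' @export
run_experiment1 <- function(cfg = study_config(), out_dir = NULL) {
  study <- study_from_config(cfg)
  tables <- list()

  within <- decode_study(study, mode = "correlation", pairing = "within_session")
  tables$within_session <- within
  between <- if (cfg$n_sessions >= 2) {
    decode_study(study, mode = "correlation", pairing = "between_session")
  } else {
    NULL
  }
  if (!is.null(between)) tables$between_session <- between

  amp <- decode_study(study, mode = "amplitude", pairing = "within_session")
  tables$amplitude_within <- amp

  # robustness check: decoding with vs without artifact rejection
  within_rej <- decode_study(study, mode = "correlation",
                             pairing = "within_session", reject = TRUE)
  tables$rejection_comparison <- tibble::tibble(
    analysis = c("no_rejection", "with_rejection"),
    mean_accuracy = c(mean(participant_means(within)),
                      mean(participant_means(within_rej)))
  )

  perms <- list()
  if (!is.null(between)) {
    pw <- permutation_test(participant_means(within), participant_means(between),
                           n_reps = cfg$n_reps_perm, seed = cfg$seed)
    perms[[length(perms) + 1]] <- tibble::tibble(
      comparison = "within_vs_between", observed_diff = pw$observed_diff,
      z = pw$z, p = pw$p
    )
  }
  pa <- permutation_test(participant_means(within), participant_means(amp),
                         n_reps = cfg$n_reps_perm, seed = cfg$seed + 1)
  perms[[length(perms) + 1]] <- tibble::tibble(
    comparison = "correlation_vs_amplitude", observed_diff = pa$observed_diff,
    z = pa$z, p = pa$p
  )
  tables$permutation_tests <- do.call(rbind, perms)

  durs <- cfg$durations[cfg$durations <= cfg$duration]
  tables$duration_sweep <- duration_sweep(study, durs, mode = "correlation",
                                          pairing = "within_session")
  centers <- cfg$band_centers[cfg$band_centers + 1 < cfg$fs / 2]
  tables$band_sweep <- band_sweep(study, centers, half_width = 1,
                                  mode = "correlation",
                                  pairing = "within_session")

  tables$alpha_power <- decode_study(study, mode = "alpha_power",
                                     pairing = "within_session")
  if (cfg$n_participants >= 2) {
    tables$identity <- identity_decode_study(study)
  }

  iaf <- iaf_table(study)
  tables$iaf <- iaf
  if (cfg$n_participants >= 3) {
    s1 <- iaf[iaf$session == 1, ]
    score <- participant_means(within)[s1$participant]
    ct <- tryCatch(correlate_scores(abs(s1$iaf_hz - cfg$flicker_freq), score),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    tables$iaf_correlation <- tibble::tibble(
      session = 1, r = ct$r, p = ct$p,
      predictor = "abs(IAF - flicker_freq)"
    )
  }

  null <- simulate_null(cfg$n_participants, cfg$n_scenes,
                        comparisons_per_scene = cfg$n_scenes - 1,
                        n_electrodes = 1, alpha_family = 0.05,
                        n_tests = cfg$bonferroni_tests,
                        n_reps = cfg$n_reps_null, seed = cfg$seed)
  tables$null_threshold <- tibble::tibble(
    threshold_percent = null$threshold_percent,
    alpha_corrected = null$alpha_corrected,
    null_mean = null$null_mean, null_sd = null$null_sd,
    n_reps = null$n_reps
  )

  bundle <- list(
    study = study, tables = tables, null = null,
    manifest = list(
      experiment = 1, seed = cfg$seed,
      design = cfg[c("n_participants", "n_scenes", "n_sessions",
                     "trials_per_scene", "flicker_freq", "duration", "fs")],
      n_recordings = length(study$recordings),
      stages = names(tables)
    )
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Run the second experiment's analysis across flicker frequencies
#'
#' Single-session studies at 1, 10 and 40 Hz flicker (5% duty cycle and
#' 100 s of stimulation at 1 Hz so the glasses flicker 100 times; 50% duty
#' and 10 s at 10 and 40 Hz), with scores averaged across the six EEG
#' electrodes, pairwise permutation tests between frequencies, the Exp-2
#' null threshold (3 scenes, Bonferroni 0.05/3), and band-pass sweeps
#' (+/- 1 Hz harmonic bands at 10 and 40 Hz; wide 10 Hz bands for 1 Hz).
#'
#' @param cfg A [study_config()]; its `n_scenes` (default here 3),
#'   participant count, noise and seed carry over. Condition-specific flicker
#'   settings are fixed by `conditions`.
#' @param conditions A tibble/data.frame with columns `flicker_freq`,
#'   `duration`, `duty_cycle` (defaults per protocol above).
#' @param band_centers Centre frequencies for the band sweeps.
#' @param out_dir Optional output directory, as in [run_experiment1()].
#' @return A result bundle: `studies` (per frequency), `tables`, `null`,
#'   `manifest`.
#' @export
run_experiment2 <- function(cfg = study_config(n_scenes = 3, n_sessions = 1,
                                               bonferroni_tests = 3),
                            conditions = tibble::tibble(
                              flicker_freq = c(1, 10, 40),
                              duration = c(100, 10, 10),
                              duty_cycle = c(0.05, 0.5, 0.5)
                            ),
                            band_centers = seq(10, 60, by = 10),
                            out_dir = NULL) {
  studies <- list()
  per_freq <- list()
  sweeps <- list()
  for (i in seq_len(nrow(conditions))) {
    f <- conditions$flicker_freq[i]
    ccfg <- cfg
    ccfg$flicker_freq <- f
    ccfg$duration <- conditions$duration[i]
    ccfg$duty_cycle <- conditions$duty_cycle[i]
    # keep the ground-truth bandwidth comparable across conditions
    ccfg$n_harmonics <- max(1, min(cfg$n_harmonics,
                                   floor((cfg$fs / 2 - 1) / f)))
    study <- study_from_config(ccfg)
    studies[[as.character(f)]] <- study
    res <- decode_study(study, mode = "correlation", pairing = "within_session")
    res$flicker_freq <- f
    per_freq[[i]] <- res

    hw <- if (f == 1) 5 else 1
    ctr <- if (f == 1) band_centers else band_centers[band_centers %% f == 0]
    ctr <- ctr[ctr - hw > 0 & ctr + hw < cfg$fs / 2]
    sw <- band_sweep(study, ctr, half_width = hw, mode = "correlation",
                     pairing = "within_session")
    sw$flicker_freq <- f
    sweeps[[i]] <- sw
  }
  tables <- list(
    per_frequency = do.call(rbind, per_freq),
    band_sweep = do.call(rbind, sweeps)
  )

  means <- lapply(per_freq, participant_means)
  names(means) <- as.character(conditions$flicker_freq)
  perm_pairs <- list(c("1", "10"), c("10", "40"))
  perms <- list()
  for (pp in perm_pairs) {
    if (all(pp %in% names(means))) {
      pt <- permutation_test(means[[pp[2]]], means[[pp[1]]],
                             n_reps = cfg$n_reps_perm, seed = cfg$seed)
      perms[[length(perms) + 1]] <- tibble::tibble(
        comparison = paste(pp[2], "vs", pp[1], "Hz"),
        observed_diff = pt$observed_diff, z = pt$z, p = pt$p
      )
    }
  }
  if (length(perms) > 0) tables$permutation_tests <- do.call(rbind, perms)

  null <- simulate_null(cfg$n_participants, cfg$n_scenes,
                        comparisons_per_scene = cfg$n_scenes - 1,
                        n_electrodes = 6, alpha_family = 0.05,
                        n_tests = cfg$bonferroni_tests,
                        n_reps = cfg$n_reps_null, seed = cfg$seed)
  tables$null_threshold <- tibble::tibble(
    threshold_percent = null$threshold_percent,
    alpha_corrected = null$alpha_corrected,
    null_mean = null$null_mean, null_sd = null$null_sd, n_reps = null$n_reps
  )

  bundle <- list(
    studies = studies, tables = tables, null = null,
    manifest = list(
      experiment = 2, seed = cfg$seed,
      conditions = as.data.frame(conditions),
      n_participants = cfg$n_participants, n_scenes = cfg$n_scenes,
      stages = names(tables)
    )
  )
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}
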