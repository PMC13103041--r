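# Duration and band-pass sweeps, plus study-level decoding behaviour.

test_that("noise-free decoding is perfect at every duration and matches the non-sweep run", {
  st <- small_study(n_participants = 2, n_scenes = 3, n_sessions = 1,
                    duration = 3, fs = 250)
  sw <- duration_sweep(st, durations = c(3, 1, 0.5, 0.2),
                       mode = "correlation", pairing = "within_session")
  expect_true(all(sw$accuracy == 100))

  direct <- decode_study(st, mode = "correlation", pairing = "within_session")
  full <- sw[sw$duration == 3, names(direct)]
  expect_equal(as.data.frame(full), as.data.frame(direct), ignore_attr = TRUE)

  expect_warning(duration_sweep(st, durations = c(1, 0.05)), "skipped")
})

test_that("accuracy grows with the amount of flicker data at realistic noise", {
  st <- small_study(n_participants = 4, n_scenes = 4, n_sessions = 1,
                    duration = 5, fs = 250,
                    noise = noise_model(broadband_rms = 20, alpha_rms = 8),
                    master_seed = 2)
  sw <- duration_sweep(st, durations = c(5, 2, 1, 0.4, 0.1),
                       mode = "correlation", pairing = "within_session")
  acc <- sapply(split(sw$accuracy, sw$duration), mean)
  durs <- as.numeric(names(acc))
  expect_gt(cor(durs, acc, method = "spearman"), 0.8)
  expect_gt(acc[durs == 5], acc[durs == 0.1])
})

test_that("group accuracy is monotone in the generator's signal-to-noise ratio", {
  acc <- vapply(c(0, 0.15, 0.6, 3), function(snr) {
    st <- small_study(n_participants = 3, n_scenes = 4, n_sessions = 1,
                      duration = 3, fs = 250,
                      noise = noise_model(broadband_rms = 15, alpha_rms = 5),
                      master_seed = 9, snr_scale = snr)
    mean(decode_study(st, mode = "correlation",
                      pairing = "within_session")$accuracy)
  }, 1)
  expect_true(all(diff(acc) >= -1)) # non-decreasing up to MC granularity
  expect_lt(abs(acc[1] - 50), 10) # zero SNR: chance
  expect_equal(acc[4], 100, tolerance = 1e-9) # high SNR: perfect
})

test_that("band sweep localises scene information placed in a single harmonic", {
  # scenes share every harmonic except the 4th (40 Hz at 10 Hz flicker)
  set.seed(31)
  base_amps <- c(5, 4, 3, 3, 2, 1.5)
  base_phases <- runif(6, 0, 2 * pi)
  waves <- list()
  for (p in c("P01", "P02")) {
    waves[[p]] <- list()
    for (s in 1:3) {
      a <- base_amps
      ph <- base_phases
      ph[4] <- 2 * pi * s / 3 + as.integer(substr(p, 2, 3)) # scene/participant specific
      waves[[p]][[paste0("scene", s)]] <- explicit_wave(a, ph, p = p,
                                                        sc = paste0("scene", s))
    }
  }
  st <- build_study_from_waves(waves, master_seed = 3)
  sw <- band_sweep(st, centers = c(10, 20, 30, 40, 50), half_width = 1,
                   mode = "correlation", pairing = "within_session")
  acc <- sapply(split(sw$accuracy, sw$center), mean)
  expect_equal(names(which.max(acc)), "40")
  expect_gt(acc["40"], 90)
  # bands without scene information hover at chance
  expect_lt(max(acc[c("10", "20", "30", "50")]), 75)
})

test_that("no single band beats broadband when information spans all harmonics", {
  st <- small_study(n_participants = 3, n_scenes = 5, n_sessions = 1,
                    duration = 3, fs = 500, n_harmonics = 8,
                    noise = noise_model(broadband_rms = 6, alpha_rms = 3),
                    master_seed = 5)
  sw <- band_sweep(st, centers = seq(10, 80, by = 10), half_width = 1,
                   mode = "correlation", pairing = "within_session")
  unfiltered <- mean(sw$accuracy[is.na(sw$center)])
  banded <- sapply(split(sw$accuracy[!is.na(sw$center)], sw$center[!is.na(sw$center)]), mean)
  expect_true(all(unfiltered >= banded))
})

test_that("bands above the informative range decode at chance", {
  # scene information only in harmonics 1-2 (10-20 Hz); harmonics 4-6 shared
  set.seed(32)
  shared_amps <- c(0, 0, 0, 3, 2, 2)
  shared_phases <- runif(6, 0, 2 * pi)
  waves <- list()
  for (p in c("P01", "P02", "P03")) {
    waves[[p]] <- list()
    for (s in 1:3) {
      a <- shared_amps + c(5, 4, 0, 0, 0, 0)
      ph <- shared_phases
      ph[1:2] <- runif(2, 0, 2 * pi)
      waves[[p]][[paste0("scene", s)]] <- explicit_wave(a, ph, p = p,
                                                        sc = paste0("scene", s))
    }
  }
  st <- build_study_from_waves(waves, master_seed = 5)
  sw <- band_sweep(st, centers = c(10, 40, 60), half_width = 1,
                   mode = "correlation", pairing = "within_session")
  acc <- sapply(split(sw$accuracy, sw$center), mean)
  expect_gt(acc["10"], 85)
  expect_gt(acc["10"], acc["40"] + 20)
  expect_lt(abs(acc["40"] - 50), 17)
  expect_lt(abs(acc["60"] - 50), 17)
})

test_that("accelerometer channels decode at chance while EEG decodes perfectly", {
  st <- small_study(n_participants = 3, n_scenes = 4, n_sessions = 1,
                    duration = 3, fs = 250,
                    noise = noise_model(broadband_rms = 5, alpha_rms = 2),
                    master_seed = 6)
  eeg <- decode_study(st, electrodes = c("O1", "O2"),
                      mode = "correlation", pairing = "within_session")
  expect_gt(mean(eeg$accuracy), 95)
  acc_res <- decode_study(st, electrodes = c("ACCx", "ACCy", "ACCz"),
                          mode = "correlation", pairing = "within_session")
  expect_lt(abs(mean(acc_res$accuracy) - 50), 15)
})

test_that("EOG decodes above chance but below occipital EEG at matched noise", {
  st <- small_study(n_participants = 3, n_scenes = 4, n_sessions = 1,
                    duration = 3, fs = 250,
                    noise = noise_model(broadband_rms = 30, alpha_rms = 0),
                    master_seed = 7)
  eeg <- decode_study(st, electrodes = c("O1", "O2"), reject = FALSE,
                      mode = "correlation", pairing = "within_session")
  eog <- decode_study(st, electrodes = c("EOGv", "EOGh"), reject = FALSE,
                      mode = "correlation", pairing = "within_session")
  expect_gt(mean(eog$accuracy), 55)
  expect_gt(mean(eeg$accuracy), mean(eog$accuracy))
})
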