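test_that("one trigger per flicker cycle: 300 at 10 Hz/30 s, 400 at 40 Hz/10 s", {
  w10 <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 8, seed = 1)
  rec10 <- synthesize_trial(w10, quiet_noise(), duration = 30, fs = 1000,
                            baseline_pre = 1, baseline_post = 0.5, seed = 1)
  expect_length(rec10$triggers, 300)

  w40 <- draw_waveform("P01", "s1", flicker_freq = 40, n_harmonics = 4, seed = 1)
  rec40 <- synthesize_trial(w40, quiet_noise(), duration = 10, fs = 1000,
                            duty_cycle = 0.5, baseline_pre = 1,
                            baseline_post = 0.5, seed = 1)
  expect_length(rec40$triggers, 400)
  # triggers aligned to each darkening: one flicker period apart
  expect_true(all(diff(rec40$triggers) == 25))
})

test_that("noise-free epoch average reproduces the ground-truth waveform", {
  w <- draw_waveform("P05", "atrium", flicker_freq = 10, n_harmonics = 6,
                     seed = 2, fs = 250)
  rec <- synthesize_trial(w, quiet_noise(), duration = 2, fs = 250,
                          baseline_pre = 1, baseline_post = 0.5, seed = 1)
  seg <- segment_recording(rec)
  avg <- average_segments(seg, "O1")
  expect_equal(avg$waveform, waveform_period(w, 250), tolerance = 1e-9)
  # per-channel gain: P7 carries the same shape scaled by its gain
  avg_p7 <- average_segments(seg, "P7")
  expect_equal(avg_p7$waveform, 0.7 * waveform_period(w, 250), tolerance = 1e-9)
})

test_that("noise-free trial spectrum is confined to flicker harmonics", {
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 5,
                     seed = 4, fs = 500)
  rec <- synthesize_trial(w, quiet_noise(), duration = 2, fs = 500,
                          baseline_pre = 0.5, baseline_post = 0.5, seed = 1)
  x <- rec$data[rec$triggers[1] + 0:999, "O1"] # exactly 20 flicker periods
  amp <- Mod(fft(x)) / length(x)
  freqs <- (seq_along(x) - 1) * 500 / length(x)
  harmonic <- freqs %% 10 == 0 & freqs > 0
  expect_gt(max(amp[harmonic]), 0.1)
  expect_lt(max(amp[!harmonic & freqs <= 250]), 1e-9)
})

test_that("accelerometer channels carry no flicker-locked component", {
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 6,
                     seed = 5, fs = 250)
  rec <- synthesize_trial(w, quiet_noise(acc_noise_rms = 1), duration = 30,
                          fs = 250, baseline_pre = 1, baseline_post = 0.5,
                          seed = 2)
  seg <- segment_recording(rec)
  for (ch in c("ACCx", "ACCy", "ACCz")) {
    avg <- average_segments(seg, ch)
    # sensor-noise average shrinks as 1/sqrt(N); flicker-locked power stays
    expect_lt(sd(avg$waveform), 3 / sqrt(300))
  }
})

test_that("blink transients straddle the 100 uV rejection threshold by design", {
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 4,
                     seed = 1, fs = 250)
  big <- synthesize_trial(w, quiet_noise(blink_rate = 0.5, blink_amp = 250),
                          duration = 20, fs = 250, baseline_pre = 1,
                          baseline_post = 1, seed = 3)
  expect_gt(length(big$meta$blink_times), 0)
  seg_big <- reject_artifacts(segment_recording(big))
  expect_gt(sum(seg_big$reject_reason == "eog"), 0)

  small <- synthesize_trial(w, quiet_noise(blink_rate = 0.5, blink_amp = 30),
                            duration = 20, fs = 250, baseline_pre = 1,
                            baseline_post = 1, seed = 3)
  seg_small <- reject_artifacts(segment_recording(small))
  expect_equal(sum(!seg_small$keep), 0)
})

test_that("invalid protocol parameters are refused", {
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 4, seed = 1)
  expect_error(synthesize_trial(w, quiet_noise(), duty_cycle = 0), "duty_cycle")
  expect_error(synthesize_trial(w, quiet_noise(), duty_cycle = 1.5), "duty_cycle")
  expect_error(synthesize_trial(w, quiet_noise(), duration = 0.05), "one flicker period")
})

test_that("make_study produces the full factorial plus eyes-closed recordings", {
  tiny <- make_study(n_participants = 1, n_scenes = 1, n_sessions = 1,
                     trials_per_scene = 1, flicker_freq = 10, duration = 1,
                     fs = 100, n_harmonics = 4, baseline_pre = 0.2,
                     baseline_post = 0.1, noise = quiet_noise(),
                     eyes_closed_duration = 1, master_seed = 1)
  expect_length(tiny$recordings, 2) # one trial + one eyes-closed

  # first experiment's shape: 20 x 6 x 2 x 2 -> 480 flicker + 40 eyes-closed
  shape <- make_study(n_participants = 20, n_scenes = 6, n_sessions = 2,
                      trials_per_scene = 2, flicker_freq = 10, duration = 0.5,
                      fs = 100, n_harmonics = 4, baseline_pre = 0.2,
                      baseline_post = 0.1, noise = quiet_noise(),
                      eyes_closed_duration = 0.5, master_seed = 1)
  md <- shape$metadata
  expect_equal(sum(md$kind == "flicker"), 480)
  expect_equal(sum(md$kind == "eyes_closed"), 40)
  # metadata rows uniquely keyed by (participant, session, scene, trial)
  keys <- with(md[md$kind == "flicker", ],
               paste(participant, session, scene, trial))
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("identical master seed reproduces a bit-identical dataset", {
  a <- small_study(noise = noise_model(broadband_rms = 5), master_seed = 42)
  b <- small_study(noise = noise_model(broadband_rms = 5), master_seed = 42)
  expect_identical(lapply(a$recordings, function(r) r$data),
                   lapply(b$recordings, function(r) r$data))
  expect_identical(a$metadata, b$metadata)
  c <- small_study(noise = noise_model(broadband_rms = 5), master_seed = 43)
  expect_false(identical(a$recordings[[1]]$data, c$recordings[[1]]$data))
})

test_that("within-session trials share a waveform; sessions differ by drift", {
  st <- small_study(n_participants = 1, n_scenes = 1, master_seed = 5)
  md <- st$metadata[st$metadata$kind == "flicker", ]
  segs <- lapply(md$idx, function(i) segment_recording(st$recordings[[i]]))
  avg <- lapply(segs, function(s) average_segments(s, "O1")$waveform)
  s1 <- which(md$session == 1)
  s2 <- which(md$session == 2)
  expect_equal(avg[[s1[1]]], avg[[s1[2]]], tolerance = 1e-9)
  expect_false(isTRUE(all.equal(avg[[s1[1]]], avg[[s2[1]]], tolerance = 1e-6)))
  expect_gt(cor(avg[[s1[1]]], avg[[s2[1]]]), 0.5) # drifted, not independent
})
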