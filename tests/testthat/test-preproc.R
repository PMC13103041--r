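test_that("segmentation yields one period-length segment per usable trigger", {
  # 30 s of 10 Hz flicker at 1000 Hz -> 300 segments of 100 samples
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 8, seed = 1)
  rec <- synthesize_trial(w, quiet_noise(), duration = 30, fs = 1000,
                          baseline_pre = 1, baseline_post = 0.5, seed = 1)
  seg <- segment_recording(rec)
  expect_equal(dim(seg$epochs)[1], 300)
  expect_equal(seg$period_samples, 100)

  # 10 s at 40 Hz -> 400 segments of 25 samples
  w40 <- draw_waveform("P01", "s1", flicker_freq = 40, n_harmonics = 4, seed = 1)
  rec40 <- synthesize_trial(w40, quiet_noise(), duration = 10, fs = 1000,
                            baseline_pre = 1, baseline_post = 0.5, seed = 1)
  seg40 <- segment_recording(rec40)
  expect_equal(dim(seg40$epochs)[1], 400)
  expect_equal(seg40$period_samples, 25)

  # 100 s at 1 Hz -> 100 segments of 1000 samples
  w1 <- draw_waveform("P01", "s1", flicker_freq = 1, n_harmonics = 24, seed = 1)
  rec1 <- synthesize_trial(w1, quiet_noise(), duration = 100, fs = 1000,
                           duty_cycle = 0.05, baseline_pre = 1,
                           baseline_post = 0.5, seed = 1)
  seg1 <- segment_recording(rec1)
  expect_equal(dim(seg1$epochs)[1], 100)
  expect_equal(seg1$period_samples, 1000)
})

test_that("segments overrunning the recording are dropped and counted", {
  x <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "O1"))
  rec <- recording(x, fs = 100, triggers = c(1, 101, 951),
                   meta = list(flicker_freq = 1))
  seg <- segment_recording(rec) # period 100: trigger at 951 overruns
  expect_equal(dim(seg$epochs)[1], 2)
  expect_equal(seg$n_dropped, 1)
})

test_that("artifact rejection applies the 100 uV EOG and 30 mg motion thresholds", {
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 4,
                     seed = 1, fs = 250)
  rec <- synthesize_trial(w, quiet_noise(), duration = 4, fs = 250,
                          baseline_pre = 1, baseline_post = 0.5, seed = 1)
  # inject one 250 uV EOG excursion inside segment 5 and one 50 mg motion
  # excursion inside segment 11
  t5 <- rec$triggers[5]
  rec$data[t5 + 3, "EOGv"] <- rec$data[t5 + 3, "EOGv"] + 250
  t11 <- rec$triggers[11]
  rec$data[t11 + 3, "ACCy"] <- rec$data[t11 + 3, "ACCy"] + 50

  seg <- reject_artifacts(segment_recording(rec))
  expect_false(seg$keep[5])
  expect_equal(seg$reject_reason[5], "eog")
  expect_false(seg$keep[11])
  expect_equal(seg$reject_reason[11], "motion")
  expect_equal(sum(!seg$keep), 2)

  # all-quiet recording: nothing rejected
  quiet <- reject_artifacts(segment_recording(
    synthesize_trial(w, quiet_noise(), duration = 4, fs = 250,
                     baseline_pre = 1, baseline_post = 0.5, seed = 2)
  ))
  expect_true(all(quiet$keep))
})

test_that("rejection never alters the stored samples", {
  w <- draw_waveform("P02", "s1", flicker_freq = 10, n_harmonics = 4,
                     seed = 1, fs = 250)
  rec <- synthesize_trial(w, quiet_noise(blink_rate = 0.5, blink_amp = 250),
                          duration = 10, fs = 250, baseline_pre = 1,
                          baseline_post = 1, seed = 4)
  seg <- segment_recording(rec)
  rejected <- reject_artifacts(seg)
  expect_gt(sum(!rejected$keep), 0)
  expect_identical(rejected$epochs, seg$epochs) # bitwise equal
})

test_that("rejection mask matches an oracle reconstructed from blink event times", {
  w <- draw_waveform("P03", "s2", flicker_freq = 10, n_harmonics = 4,
                     seed = 6, fs = 250)
  fs <- 250
  rec <- synthesize_trial(w, quiet_noise(blink_rate = 0.3, blink_amp = 180),
                          duration = 20, fs = fs, baseline_pre = 1,
                          baseline_post = 1, seed = 7)
  expect_gt(length(rec$meta$blink_times), 0)

  # reconstruct the noise-free EOG traces from first principles: attenuated
  # flicker waveform plus the blink template (full on EOGv, 30% on EOGh) at
  # each event onset
  n <- nrow(rec$data)
  trig0 <- rec$triggers[1]
  fl_idx <- trig0:(trig0 + 20 * fs - 1)
  flicker_part <- numeric(n)
  flicker_part[fl_idx] <- 0.4 * eval_waveform(w, (fl_idx - trig0) / fs)
  blink_part <- numeric(n)
  tmpl <- blink_template(fs) * 180
  for (tt in rec$meta$blink_times) {
    i0 <- round(tt * fs) + 1
    idx <- i0:(i0 + length(tmpl) - 1)
    ok <- idx <= n
    blink_part[idx[ok]] <- blink_part[idx[ok]] + tmpl[ok]
  }
  trace_v <- flicker_part + blink_part
  trace_h <- flicker_part + 0.3 * blink_part
  p <- round(fs / 10)
  ptp_in_seg <- function(trace, tg) {
    seg <- trace[tg:(tg + p - 1)]
    max(seg) - min(seg)
  }
  expected_reject <- vapply(rec$triggers, function(tg) {
    ptp_in_seg(trace_v, tg) > 100 || ptp_in_seg(trace_h, tg) > 100
  }, logical(1))

  seg <- reject_artifacts(segment_recording(rec))
  expect_identical(unname(!seg$keep), unname(expected_reject))
})

test_that("band-pass keeps the centre frequency and attenuates out-of-band input", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  mid <- (3 * fs):(7 * fs) # away from edge transients
  inband <- single_channel_recording(sin(2 * pi * 40 * t), fs)
  out <- bandpass_filter(inband, center = 40, half_width = 1)
  expect_lt(abs(max(abs(out$data[mid, 1])) - 1), 0.01) # within 1%

  faroff <- single_channel_recording(sin(2 * pi * 50 * t), fs)
  outf <- bandpass_filter(faroff, center = 40, half_width = 1)
  atten_db <- 20 * log10(max(abs(outf$data[mid, 1])))
  expect_lt(atten_db, -20)

  dc <- single_channel_recording(rep(3, 5 * fs), fs)
  outdc <- bandpass_filter(dc, center = 40, half_width = 1)
  expect_lt(max(abs(outdc$data[(2 * fs):(3 * fs), 1])), 1e-3)
})

test_that("band-pass filtering is linear and validates its band edges", {
  fs <- 500
  x <- rnorm(5 * fs)
  r1 <- bandpass_filter(single_channel_recording(x, fs), 40, 2)
  r3 <- bandpass_filter(single_channel_recording(3 * x, fs), 40, 2)
  expect_equal(r3$data, 3 * r1$data, tolerance = 1e-6)

  expect_error(bandpass_filter(single_channel_recording(x, fs), 0.5, 1),
               "positive")
  expect_error(bandpass_filter(single_channel_recording(x, fs), 249, 2),
               "Nyquist")
})

test_that("50 Hz notch removes mains frequency and spares the flicker response", {
  fs <- 1000
  t <- (0:(10 * fs - 1)) / fs
  mid <- (3 * fs):(7 * fs)

  mains <- single_channel_recording(sin(2 * pi * 50 * t), fs)
  out50 <- notch_filter(mains)
  expect_lt(sd(out50$data[mid, 1]) / sd(mains$data[mid, 1]), 0.05)

  flick <- single_channel_recording(sin(2 * pi * 10 * t), fs)
  out10 <- notch_filter(flick)
  expect_lt(abs(max(abs(out10$data[mid, 1])) - 1), 0.01)

  silent <- single_channel_recording(numeric(fs), fs)
  expect_equal(max(abs(notch_filter(silent)$data)), 0)
})

test_that("filtering excludes edge-transient triggers from segmentation", {
  w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 4,
                     seed = 1, fs = 250)
  # baseline 0.5 s < 1 s edge guard: early/late triggers must be dropped
  rec <- synthesize_trial(w, quiet_noise(), duration = 4, fs = 250,
                          baseline_pre = 0.5, baseline_post = 0.5, seed = 1)
  plain <- segment_recording(rec)
  filt <- segment_recording(bandpass_filter(rec, 10, 1))
  expect_lt(dim(filt$epochs)[1], dim(plain$epochs)[1])
  expect_gt(filt$n_dropped, 0)
})
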