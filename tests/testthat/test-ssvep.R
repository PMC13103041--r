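test_that("averaging identical segments returns that segment exactly", {
  truth <- sin(2 * pi * (0:99) / 100)
  seg <- manual_segment_set(matrix(truth, 300, 100, byrow = TRUE))
  avg <- average_segments(seg, "O1")
  expect_equal(avg$waveform, truth, tolerance = 1e-12)
  expect_equal(avg$n_segments_used, 300)
})

test_that("max_duration truncates to the first flickers: 0.3 s at 10 Hz = 3 segments", {
  ep <- matrix(rnorm(300 * 100), 300, 100)
  seg <- manual_segment_set(ep) # triggers every 0.1 s
  avg <- average_segments(seg, "O1", max_duration = 0.3)
  expect_equal(avg$n_segments_used, 3)
  expect_equal(avg$waveform, colMeans(ep[1:3, ]), tolerance = 1e-12)
  # full duration reproduces the untruncated average
  expect_equal(average_segments(seg, "O1", max_duration = 30)$waveform,
               average_segments(seg, "O1")$waveform)
  expect_error(average_segments(seg, "O1", max_duration = 0), "max_duration")
})

test_that("averaging is permutation-invariant over segments", {
  ep <- matrix(rnorm(50 * 100), 50, 100)
  seg <- manual_segment_set(ep)
  shuffled <- manual_segment_set(ep[sample.int(50), ])
  expect_equal(average_segments(seg, "O1")$waveform,
               average_segments(shuffled, "O1")$waveform, tolerance = 1e-12)
})

test_that("residual noise after averaging N epochs scales as sigma/sqrt(N)", {
  set.seed(11)
  truth <- 5 * sin(2 * pi * (0:99) / 100)
  sigma <- 10
  n_seg <- 300
  ratio <- vapply(1:10, function(i) {
    ep <- matrix(rep(truth, each = n_seg) + rnorm(n_seg * 100, 0, sigma),
                 n_seg, 100)
    rms_dev <- sqrt(mean((average_segments(manual_segment_set(ep), "O1")$waveform - truth)^2))
    rms_dev / (sigma / sqrt(n_seg))
  }, 1)
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("comb-filter attenuation of a non-harmonic sinusoid matches the Dirichlet kernel", {
  fs <- 1000
  f_flick <- 10
  p <- fs / f_flick
  n_seg <- 50 # chosen so the Dirichlet factor is small but well above eps
  for (f0 in c(12.35, 23.7, 41.3)) {
    t <- (0:(n_seg * p - 1)) / fs
    x <- sin(2 * pi * f0 * t)
    ep <- matrix(x, n_seg, p, byrow = TRUE)
    avg <- average_segments(manual_segment_set(ep, fs = fs), "O1")$waveform
    got <- fitted_amplitude(avg, f0, fs)
    theta <- pi * f0 * p / fs
    expected <- abs(sin(n_seg * theta) / (n_seg * sin(theta)))
    expect_lt(abs(got - expected) / expected, 0.01)
  }
})

test_that("averaging reproduces the generator's waveform on noise-free input", {
  st <- small_study(n_participants = 1, n_scenes = 2, n_sessions = 1)
  md <- st$metadata[st$metadata$kind == "flicker", ]
  for (i in seq_len(nrow(md))) {
    seg <- segment_recording(st$recordings[[md$idx[i]]])
    avg <- average_segments(seg, "O1")$waveform
    truth <- waveform_period(st$waveforms[[md$participant[i]]][[md$scene[i]]][[1]],
                             st$config$fs)
    expect_gt(cor(avg, truth), 0.999)
  }
})

test_that("peak-to-peak amplitude behaves as max minus min", {
  expect_equal(peak_to_peak(rep(2.5, 100)), 0)
  s <- sin(2 * pi * (0:999) / 1000)
  expect_equal(peak_to_peak(s), 2, tolerance = 1e-4)
  x <- rnorm(100)
  expect_equal(peak_to_peak(3.7 * x), 3.7 * peak_to_peak(x), tolerance = 1e-12)
})

test_that("baseline alpha spectrum has 0.25 Hz resolution and finds the peak", {
  fs <- 250
  t <- (0:(6 * fs - 1)) / fs
  rec <- single_channel_recording(4 * sin(2 * pi * 10 * t) + 1.5, fs)
  sp <- baseline_alpha(rec, "O1")
  expect_equal(diff(sp$freqs[1:2]), 0.25)
  expect_equal(sp$peak_freq, 10)
  expect_gt(sp$peak_amp, 1)

  # pre-flicker period shorter than 5 s is refused
  short <- single_channel_recording(rnorm(6 * fs), fs, triggers = 3 * fs)
  expect_error(baseline_alpha(short, "O1"), "5 s")
})

test_that("white-noise alpha peaks favour no frequency bin", {
  fs <- 250
  set.seed(21)
  peaks <- vapply(1:1000, function(i) {
    rec <- single_channel_recording(rnorm(5 * fs), fs)
    baseline_alpha(rec, "O1")$peak_freq
  }, 1)
  counts <- table(factor(peaks, levels = seq(8, 14, by = 0.25)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("individual alpha frequency is recovered from eyes-closed data", {
  nm <- noise_model(broadband_rms = 2, alpha_freq = 10.5, alpha_rms = 8)
  rec <- synth_eyes_closed(nm, duration = 30, fs = 250, seed = 3)
  expect_equal(estimate_iaf(rec), 10.5, tolerance = 0.26)

  # argmax picks the larger of two alpha-band sinusoids
  fs <- 250
  t <- (0:(8 * fs - 1)) / fs
  x <- 5 * sin(2 * pi * 9 * t) + 2 * sin(2 * pi * 12 * t)
  expect_equal(estimate_iaf(single_channel_recording(x, fs),
                            electrodes = "O1"), 9)

  # degenerate flat input still lands inside the alpha search band
  flat <- synth_eyes_closed(noise_model(broadband_rms = 1, alpha_rms = 0),
                            duration = 8, fs = 250, seed = 4)
  iaf <- estimate_iaf(flat)
  expect_gte(iaf, 8)
  expect_lte(iaf, 14)

  expect_error(estimate_iaf(rec, electrodes = c("O1", "Oz")), "Oz")
})

test_that("alpha peak amplitude grows with the generator's alpha power", {
  peaks <- vapply(c(0, 2, 6, 12), function(a) {
    nm <- noise_model(broadband_rms = 2, alpha_freq = 10, alpha_rms = a)
    w <- draw_waveform("P01", "s1", flicker_freq = 10, n_harmonics = 4,
                       seed = 1, fs = 250)
    rec <- synthesize_trial(w, nm, duration = 1, fs = 250, baseline_pre = 6,
                            baseline_post = 0.5, seed = 5)
    baseline_alpha(rec, "O1")$peak_amp
  }, 1)
  expect_true(all(diff(peaks) > 0))
})
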