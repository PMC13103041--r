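# ssvepshape

Decoding real-world visual scenes — and participant identity — from the
**waveform shape** of steady-state visually evoked potentials (SSVEPs)
recorded with flickering LCD glasses.

When a scene is viewed through glasses flickering at 10 Hz, averaging the
EEG into trigger-locked epochs of one flicker period (100 ms) yields an
SSVEP whose shape is a stable fingerprint of scene and viewer. The core
decoder scores pairwise comparisons: scene *L* decodes correctly against
scene *M* when the baseline correlation `r(x_L, y_L)` between two trials of
the same scene strictly exceeds the cross-scene correlation `r(x_M, y_L)`.
With 6 scenes each electrode receives a score out of 5 per scene (30 in
total); accuracy is the percentage of correct comparisons, with 50% chance.
Because Pearson correlation ignores scale and offset, the decision rests on
shape alone — the contrast with conventional peak-to-peak amplitude decoding
is itself one of the analyses.

The package implements the complete chain, for recorded data (BrainVision
`.vhdr/.vmrk/.eeg` or delimited text) and for a synthetic generator that
emulates the study's signal structure (per participant x scene harmonic
waveforms, 1/f noise, individual alpha oscillators, blinks, motion bursts,
session-to-session drift):

* `io` / preprocessing: `read_recording()`, `segment_recording()`,
  `reject_artifacts()` (100 µV EOG / 30 mg accelerometer peak-to-peak),
  zero-phase `bandpass_filter()` (4th-order Butterworth, ±1 Hz harmonic
  bands) and `notch_filter()` (50 Hz, Q = 30)
* SSVEPs: `average_segments()`, `peak_to_peak()`, `baseline_alpha()`
  (4 s Hann window, 0.25 Hz resolution), `estimate_iaf()`
* decoding: `correlation_decode()`, `amplitude_decode()`,
  `alpha_power_decode()`, `identity_decode()`, study-level `decode_study()`,
  `duration_sweep()`, `band_sweep()`
* statistics: `simulate_null()` (100,000-rep chance-level null with
  Bonferroni-corrected significance thresholds), `permutation_test()`
  (paired sign flips), `correlate_scores()`
* orchestration: `make_study()`, `run_experiment1()`, `run_experiment2()`

## Worked example

```r
library(ssvepshape)

# a small synthetic study: 2 participants x 3 scenes x 2 sessions,
# two 3 s trials per scene at 10 Hz flicker
study <- make_study(n_participants = 2, n_scenes = 3, n_sessions = 2,
                    trials_per_scene = 2, duration = 3, fs = 250,
                    n_harmonics = 6, baseline_pre = 5, baseline_post = 0.5,
                    noise = noise_model(broadband_rms = 10), master_seed = 1)

within <- decode_study(study, mode = "correlation", pairing = "within_session")
summarize_decoding(within)
#> # A tibble: 1 × 3
#>   mean_accuracy median_accuracy     n
#>           <dbl>           <dbl> <int>
#> 1          93.8            93.8     2

nd <- simulate_null(20, 6, 5, n_electrodes = 1, alpha_family = 0.05,
                    n_tests = 8, n_reps = 100000, seed = 1)
nd
#> <null_distribution> 100000 reps, 600 comparisons; mean 50.00%, sd 2.047; threshold 55.17% at alpha 0.00625
```

Three seconds of flicker at this noise level decode the scenes at 93.8%;
the null distribution says a group-average score above ~55.1% across 20
participants is significant at the Bonferroni-corrected alpha
0.05/8 = 0.00625.

## The analysis workflow

`analysis/01_simulate_study.R` … `06_experiment2.R` run the full study
pipeline on a scaled synthetic dataset (6 participants, 6 scenes, 2
sessions, 15 s trials; see the methods vignette for the sizing rationale)
and write tidy tables under `results/`. From the repository root:

```sh
Rscript analysis/01_simulate_study.R   # simulate + IAF recovery
Rscript analysis/02_decode_scenes.R    # within/between, amplitude, rejection, permutations
Rscript analysis/03_alpha_identity.R   # alpha-power + identity decoding
Rscript analysis/04_sweeps.R           # duration sweep + harmonic band sweep
Rscript analysis/05_significance.R     # null thresholds + IAF correlation
Rscript analysis/06_experiment2.R      # 1/10/40 Hz flicker comparison
```

Representative output from this configuration (printed by the scripts):

```
group mean accuracy, within-session: 93.4%
group mean accuracy, between-session: 82.3%
group mean accuracy, amplitude decoding: 73.3%
within vs between: diff 11.2 pp, Z = 2.33, p = 0.01
correlation vs amplitude: diff 20.1 pp, Z = 2.30, p = 0.011
alpha-power decoding, group mean: 51.0% (pairwise chance 50%)
participant-identity decoding: 73.6% mean across scenes/electrodes (chance 16.7%)
unfiltered accuracy: 93.4%  |  best single band: 10 Hz (78.0%)
significance thresholds: 55.17% (design 1), 54.03% (design 2)
```

Waveform-shape decoding beats amplitude decoding, within-session beats
between-session, no single frequency band matches the broadband waveform,
accelerometer channels sit at chance, and the pre-flicker alpha power
carries almost no scene information — the qualitative structure the
pipeline is designed to measure.

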