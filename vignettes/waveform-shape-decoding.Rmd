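---
title: "Decoding visual scenes from SSVEP waveform shape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual scenes from SSVEP waveform shape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepshape)
```

## The problem

When a person views a scene through glasses that flicker periodically (LCD
shutter glasses darkening at, say, 10 Hz), the visual system produces a
steady-state visually evoked potential (SSVEP): a periodic EEG response at
the flicker frequency and its harmonics. Averaging the EEG cut into
one-flicker-period epochs, locked to the darkening triggers, isolates this
response — averaging N epochs acts as a comb filter that retains only the
flicker frequency and its harmonics while everything else shrinks.

The scientific claim this package operationalises is that the *shape* of
that one-period waveform — not merely its amplitude — is a rich fingerprint
of both the visual scene being viewed and the person viewing it. `ssvepshape`
implements the full analysis chain: segmentation and artifact handling,
epoch averaging, a score-based Pearson-correlation decoder with several
comparison variants, duration and band-pass sweeps, and the significance
machinery (simulated nulls, Bonferroni correction, sign-flip permutation
tests). A synthetic-EEG generator with the same statistical structure makes
every stage runnable and testable without any recorded data.

## The decoder

For a given electrode and participant, each scene $L$ has an SSVEP from a
baseline trial ($x_L$) and from a test trial ($y_L$). The *baseline
correlation* is the Pearson correlation $r(x_L, y_L)$. For every other scene
$M \ne L$, a point is awarded iff

$$ r(x_L, y_L) > r(x_M, y_L), $$

with strict inequality: ties (and correlations undefined because a waveform
is constant, which aggressive band-pass filtering can produce) never score.
With 6 scenes each electrode collects a score out of 5 per scene, 30 per
comparison round, and the accuracy is `100 * correct / total`. Because
Pearson correlation is invariant to positive scaling and offsets, the
decision depends on waveform shape alone — the property that distinguishes
this decoder from the conventional peak-to-peak amplitude measure
(`amplitude_decode()`, same scoring on $|\Delta\,\mathrm{ptp}|$).

Two further variants share the scoring rule: decoding from the peak alpha
amplitude of the pre-flicker baseline (`alpha_power_decode()`), and
winner-take-all participant-identity decoding (`identity_decode()`), where a
participant's test SSVEP must correlate better with their own baseline SSVEP
than with any other participant's; its chance level is $100/n$ percent
(5% for 20 participants).

### Scoring convention

One comparison round per trial pair: the earlier trial is the baseline, the
later the test. With 6 scenes this gives the canonical score out of 30 per
electrode, and with 3 scenes a score out of 6 ("two for each location").
`pool_orderings = TRUE` optionally adds the reversed ordering; it doubles the
denominator without changing chance level, and is off by default so the
printed score maxima match the canonical design. Accuracies are aggregated
per participant and electrode first, then averaged across electrodes to one
score per participant, then across participants (`summarize_decoding()`
reports both mean and median).

## Significance machinery

Under the null every pairwise comparison is a fair coin. `simulate_null()`
draws `n_reps` replicates of the group-average accuracy over
$N = \text{participants} \times \text{scenes} \times \text{comparisons}
\times \text{electrodes}$ Bernoulli(0.5) outcomes, computes the empirical
mean and SD, assigns a Z and one-sided normal-tail p to every *achievable*
score (the group average is discrete with step $100/N$), and reports the
smallest achievable score with $p$ below the Bonferroni-corrected alpha.
Because the real aggregation is an equal-weight mean over all comparisons,
the group-average accuracy is exactly a scaled Binomial($N$, 0.5) draw; the
implementation samples it directly, which is distributionally identical to
drawing the full factorial array and aggregating, at a fraction of the cost.

Two design choices deserve note:

* **Z-based p-values.** p comes from the normal tail of the empirical
  Z-score, not from the empirical rank of the null sample. Empirical ranks
  saturate at $1/\text{n\_reps}$; the Z-based rule matches the reported
  threshold behaviour and extrapolates smoothly.
* **Thresholds on the score grid.** For the 20 x 6 x 5 single-electrode
  design at alpha 0.05/8 the threshold lands at 55.17% (grid step 1/6
  percentage point); for the 20 x 3 x 2 six-electrode design at 0.05/3 it
  lands at 54.03% (grid step 0.139). The second design's normal-tail
  criterion sits just below one grid point, so implementations differing
  only in continuity handling or in SD jitter report values one step apart;
  this package reports the grid value implied by the uncorrected normal
  tail.

The paired comparison between analysis conditions (within- vs
between-session, correlation vs amplitude, flicker frequencies) uses a
sign-flip permutation test: each participant's pair of labels is swapped
with probability one half, `n_reps` times, and the observed mean difference
is normalised by the null's mean and SD; for $n \le 12$ this matches exact
enumeration of all $2^n$ sign patterns, which the test suite verifies.
Correlations between per-participant scalars (e.g. decoding score vs the
distance between individual alpha frequency and the flicker frequency) use
the Pearson correlation with the usual $t$-based two-sided p.

A note on one arithmetic detail: the per-session decoding score summed over
6 scenes, 6 electrodes and 5 comparisons has a maximum of
$6 \times 6 \times 5 = 180$ points, and that is what the package computes;
larger printed maxima sometimes quoted for this design do not correspond to
any combination of these factors.

## Preprocessing

* **Segmentation** starts each epoch at the trigger sample, with length
  `round(fs / flicker_freq)` samples and no pre-trigger offset; the decoder
  only needs a phase reference that is consistent across trials. Epochs that
  would overrun the recording are dropped and counted. No cumulative drift
  can build up because every epoch starts at an actual trigger.
* **Artifact rejection** (`reject_artifacts()`) drops an epoch when the
  within-epoch peak-to-peak amplitude exceeds 100 microvolts on either EOG
  channel or 30 mg on any accelerometer axis. It never touches the stored
  samples. The *main* decoding applies no rejection and no filters — the
  with/without-rejection contrast is itself one of the robustness analyses —
  so `decode_study(reject = FALSE)` is the default.
* **Filters** are applied to the continuous data before segmentation: a
  4th-order Butterworth band-pass at `center +/- half_width` Hz and a
  second-order IIR notch at 50 Hz with quality factor 30. Both are run
  forwards and backwards (zero phase). Whether the original analyses were
  zero-phase is not documented; zero phase keeps filtered SSVEPs aligned
  with unfiltered ones, and since the decoder compares shapes across trials
  any consistent phase convention gives identical scores. After filtering,
  triggers within one second of either end of the recording are excluded
  from segmentation to avoid edge transients; with the protocol's 5 s
  baselines this excludes nothing.
* **Spectra** use mean subtraction ("baseline corrected" read as removing
  the window mean — the simplest reading, and the Hann window suppresses any
  residual slow drift), a Hann window, and a one-sided amplitude convention
  of $2|X_k|/N$. A 4 s window gives the 0.25 Hz resolution used throughout.
  The individual alpha frequency averages spectra over seven non-overlapping
  4 s windows of the 30 s eyes-closed recording and over the six EEG
  electrodes (the windowing of the 30 s recording is a package choice), and
  takes the 8-14 Hz argmax with ties broken toward the lower frequency.

## The synthetic generator

`make_study()` emulates the study's signal structure:

* Each (participant, scene) pair owns a periodic ground-truth waveform:
  amplitudes $a_k \propto k^{-\gamma}$ times a lognormal factor, phases
  uniform. Defaults: $\gamma = 1$, $K = 24$ harmonics (10-240 Hz at 10 Hz
  flicker — the range the band-sweep probes; information in real data fades
  above roughly 180 Hz), first-harmonic scale 5 microvolts, lognormal sdlog
  0.8. The harmonic-envelope form is an assumption — the real distribution
  of waveform shapes is not characterised beyond example traces — and is
  flagged as such.
* The waveform enters the six EEG channels with per-channel gains (occipital
  strongest) and the EOG channels at gain 0.4, so EOG decodes above chance
  but worse than EEG. Accelerometer channels carry no flicker-locked
  component at all, guaranteeing chance-level decoding there.
* Background activity per channel: $1/f$ noise (default exponent 1, RMS 10
  microvolts) plus a narrow-band alpha oscillator at a per-participant
  frequency drawn from Normal(10.275, 0.843) Hz clamped to [8, 14] —
  the reported population distribution — with eyes-closed recordings
  doubling the alpha amplitude.
* Artifacts: biphasic 400 ms blinks (Poisson rate 0.2/s, 250 microvolts on
  vertical EOG, 30% on horizontal EOG, 10% on EEG) and 1-2 s smoothed
  random-walk motion bursts (rate 0.05/s, 50 mg peak). Both default above
  the rejection thresholds so threshold logic can be tested from both sides
  by scaling them.
* Between sessions, waveforms drift on their complex harmonic coefficients:
  $c_2 = s\,c_1 + \sqrt{1 - s^2}\,c_\perp$ with an independent redraw
  $c_\perp$ and a lognormal session gain. The expected waveform correlation
  across sessions is approximately $s$ (default 0.9), reproducing the
  within- vs between-session accuracy gap.
* Seeding: one master seed; every waveform, trial, blink and drift stream
  derives a child seed from a polynomial hash of its labels, so the same
  configuration is bit-identical regardless of evaluation order.

What the generator does **not** emulate: volume-conduction geometry (channel
correlations beyond shared signal), eye movements other than blinks,
non-stationary noise levels, line noise, or any relationship between scene
content and waveform shape. Passing tests on synthetic data therefore
demonstrate the correctness and calibration of the *pipeline* — chance
levels, thresholds, monotonic SNR/duration behaviour, band localisation —
not the empirical decodability of real scenes, whose accuracies depend on
the recorded EEG.

## Numerical and degenerate-input choices

* Ties in any decoder score no point (strict inequality); zero-variance
  waveforms yield undefined correlations which are counted incorrect and
  flagged, never raised as errors that would kill a sweep.
* Identity decoding counts a tie for the maximum as incorrect.
* `estimate_iaf()` on a flat spectrum still returns a value inside [8, 14]
  (the argmax of noise) — documented degenerate behaviour.
* The permutation test returns $z = 0$, $p = 1$ and a degeneracy flag when
  all paired differences are zero.
* The duration sweep skips durations below one flicker period with a
  warning; the band sweep skips bands whose edges reach Nyquist.
* Narrow +/-1 Hz Butterworth bands at 1000 Hz sampling were verified
  numerically stable in double precision (passband within 1%, no
  divergence); the 50 Hz notch is the standard constrained biquad.

## Problem sizes

The bundled analysis scripts (`analysis/01_simulate_study.R` ...
`06_experiment2.R`) run the whole chain on a scaled study: 6 participants,
6 scenes, 2 sessions, two 15 s trials per scene at 250 Hz sampling with 12
harmonics, and evoked amplitudes scaled by 0.35 so group scores sit in the
80-95% range rather than at ceiling. These sizes are the package's choice
for a demonstration that a laptop reproduces in a few minutes; the full
protocol (20 participants, 30 s trials, 1000 Hz, 24 harmonics) is the
generator default and runs the same code. Null distributions and
permutation tests always use the full 100,000 replicates — they are cheap.

## Known limitations

* The decoder is closed-set: the same scenes appear in baseline and test
  trials; nothing here generalises to unseen scenes.
* No time-frequency analysis, cycle-asymmetry metrics, ICA, re-referencing
  or channel interpolation; no online/real-time loop.
* BrainVision support covers the multiplexed binary layout (IEEE float32 /
  int16) that the recording software writes; vectorised or ASCII layouts are
  out of scope.
* The simulated null assumes independent comparisons; real pairwise scores
  share SSVEPs across comparisons, which the null ignores exactly as the
  original procedure does.
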