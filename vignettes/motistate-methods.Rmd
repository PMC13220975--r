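---
title: "Models and methods behind motistate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motistate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`motistate` analyzes head-fixed go/no-go training at the level of
*motivation states*: multi-trial stretches in which a mouse licks
indiscriminately (persistent), stops licking (disengaged), or discriminates
well (attentive). This vignette explains the models and procedures the
package implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The task and its timing

Each daily session is a pseudorandom sequence of 500 go/no-go trials with
no more than three consecutive repetitions of the same type, implemented by
rejecting (re-flipping) any draw that would create a fourth repetition.
Counts are therefore approximately, not exactly, balanced. A trial is
1 s prestimulus, 0.2 s stimulus, 1.8 s answer period and 2 s intertrial
interval — 5 s in total — and a false alarm extends the intertrial interval
to 10 s (a 13 s trial). Throughout the package the *punishment period* is
defined as the extension beyond the standard 5 s span: whole-trial lick
rates always use the 5 s span (so punishment is excluded by construction),
and eye-video frames falling inside the extension are dropped.

## State labeling

Whole-trial lick rate (Hz, licks in the 5 s span / 5) and binary
correctness (hit or correct rejection = 1) are smoothed with a 50-trial
centered moving mean progressing in 1-trial steps. The window shrinks at
session edges so that output length equals input length and no smoothing
crosses a day boundary. The smoothed vectors are concatenated across days
per mouse and binarized:

* licking: a 100-bin equal-width histogram over the observed range; trials
  at or below the upper edge of the second bin are *low/no licking*;
* correctness: trials at or above the mouse's 75th sample quantile
  (linear-interpolation definition, ties inclusive) are *good performance*.
  The cutoff is always per mouse, never pooled.

Good performance maps to attentive; remaining low/no-licking trials to
disengaged; the rest to persistent. The (low/no licking, good performance)
combination did not occur in the recordings this analysis was designed for;
when it occurs, attentive takes precedence (the state is defined by
performance) and the pipeline counts the conflicts, warning above 1%.

Because the quantile is fixed at 0.75, the labeled attentive fraction is
exactly 25% per mouse. Agreement with a latent ground truth therefore
degrades whenever the true attentive prevalence departs from ~25% — a
property worth remembering when interpreting the synthetic benchmarks.

## State prediction

The classifier input is one table per mouse: rows are concatenated trials,
columns the eight nonperformance variables, each smoothed with the same
50-trial session-wise moving mean. To deconstruct the autocorrelation that
smoothing introduces, rows are shuffled in consecutive blocks of 25 trials
(block order permuted, within-block order kept), split 1:1, and a bagged
ensemble of 30 fully grown decision trees (`randomForest` with
`mtry = p`, `nodesize = 1` — bagging, no feature subsampling) is trained on
each half and scores the other; the two held-out halves are recombined in
chronological order. The class score is the fraction of tree votes, the
natural bagged-ensemble score. If a rare state is missing from a training
half after 20 shuffle attempts, a stratified split is used with a warning.

One-vs-rest ROC curves pool the (score, label) pairs of a whole iteration
group (default 100 iterations per predictor-pool size; tied scores move as
one group, making the trapezoid equal to the mid-rank Mann–Whitney
statistic). Per-iteration AUC averaging is available
(`aggregate = "mean"`), but pooling is the default. AUC versus pool size
(1–8 variables drawn without replacement per iteration) is fitted with the
asymptotic exponential `y = a − b exp(−k x)` by Levenberg–Marquardt least
squares with multi-start over `k`; the p-value for `k` uses the asymptotic
normal approximation from the Jacobian-based covariance. Degenerate curves
(constant AUC) are flagged rather than fitted.

Controls follow the same machinery: cross-mouse transfer trains on one
mouse's shuffled half and scores a size-matched held-out set from another
mouse (all ordered pairs); row shuffling permutes trial order only; full
shuffling additionally permutes every predictor column independently,
destroying the feature–state pairing and collapsing AUC to 0.5; subset
modes restrict pools to the behavioral (lick/wheel/eye) or
neurophysiological (PSS/LFP/MUA) variables. The GLM control predicts
smoothed correctness from seven of the eight predictors (one omitted per
iteration, intercept always removed) and accumulates t-statistics; the
multinomial control predicts the three states with a rotated reference
category; both are repeated with a shuffled response and compared with
Friedman tests across predictors plus Tukey-protected paired post hocs.
The control simulations in the test suite use the generator's ground-truth
states as the prediction target, decoupling classifier behavior from
labeling noise.

## Feature definitions

* **Wheel speed**: encoder voltage (0–3.3 V) is rescaled to 0–36 cm — the
  stated calibration range of the wheel, which is kept as authoritative
  even though a 13 cm wheel diameter would imply ~40.8 cm — unwrapped
  across the wrap boundary into a monotone distance curve and
  differentiated. Speed is signed; backward running is negative, and the
  whole-trial value is the signed mean (consistent with analyzing backward
  running as its own phenomenon).
* **Pupil / eyelid**: per video frame, the aperture is the Euclidean
  distance (hypotenuse) between the topmost and bottommost vertices of the
  8-point keypoint octagon; per trial, the mean over frames in the trial
  span excluding the punishment extension. Trials with no valid frames
  receive the session median, flagged — the classifier requires complete
  rows.
* **PSS**: per channel, a Welch density of the 1 s prestimulus LFP (Hann
  taper, 1 s window, 50% overlap — a single segment on a 1 s epoch),
  interpolated onto 100 log-spaced bin centers spanning 1–100 Hz
  (interpolation linear in the log–log axes; the resampling method is a
  package choice), log10-transformed and fitted with a least-squares line;
  slopes averaged across channels.
* **MUA band power**: per-channel Welch density (0.5 s window, 50%
  overlap), interpolated onto 500, 1000, …, 5000 Hz centers and summed;
  averaged across channels. Requires at least a 10 kHz sampling rate.
* **Evoked responses**: channel-and-time mean LFP over the 200 ms stimulus
  window; evoked MUA uses the same band-power reduction with a 50 ms Welch
  window, since a 0.5 s window cannot fit a 200 ms epoch.

The Welch and short-time-spectrogram primitives are implemented in the
package (one-sided densities normalized so white noise of variance s² at
rate fs has density 2s²/fs) and are validated in the tests against a direct
DFT oracle and against Parseval scaling.

## Training progression

States are crossed with outcomes and the eight plausible combinations kept
(persistent × hit/false-alarm, attentive × all four, disengaged ×
correct-rejection/miss); the rare incongruent combinations are dropped with
counts reported. Each subcategory is split chronologically into 99 blocks
as equal as possible — remainder trials are assigned one each to the
earliest blocks, a deterministic, order-preserving rule — and the blocks
grouped into early/mid/late stages of 33. Peristimulus traces are
resampled onto 80 bins spanning [−1, +4] s (62.5 ms bins; the bin count is
chosen so that the repeated-measures degrees of freedom match a 79-step
time axis, and is configurable). Wheel speed is mean-subtracted by its own
prestimulus mean; eye signals are z-scored by prestimulus mean and SD with
a floor of 10⁻⁶ × the trace range so flat traces stay finite; lick rate is
left raw.

Stage effects are tested with a two-way mixed ANOVA: stage is between
units, the repeated measure (time bins, or depth channels in the laminar
version) within units, where a unit is one trial block, pooled across mice.
The stage effect is tested against the between-unit stratum and the
repeated-measure and interaction effects against the within-unit stratum
(`aov` with an `Error(unit/bin)` structure, verified against a direct
sums-of-squares decomposition). Tukey HSD compares stages at each
repeated-measure level, protected by the omnibus stage or interaction test;
no additional across-bin correction is applied, matching the
per-bin-flag presentation style. The exact error degrees of freedom
reported for the original recordings cannot be reconstructed unambiguously
from 33 blocks × mice × 3 stages; blocks-as-units is used and this
discrepancy is a known limitation.

## Laminar analysis

Epochs of [−0.05, +0.25] s around stimulus onset are processed per trial:

* **CSD**: second spatial difference across channels (edge channels
  replicate the nearest interior value to preserve the channel count),
  z-scored per channel over the epoch (all-constant channels are left at
  zero and flagged), then smoothed across 5 channels and 20 ms.
  Conductivity and spacing constants are omitted: profiles are z-scored and
  min–max normalized, so physical units cancel.
* **MUA**: per-channel spectrogram (4 ms Hann windows, 50% overlap),
  absolute power summed over the 500–5,000 Hz bins, z-scored per channel,
  smoothed over 10 ms, no spatial smoothing.

Depth profiles take absolute values (sinks and sources contribute equally),
average 0–100 ms post-stimulus, subtract a centered 22-channel moving mean
(centered, for symmetric trend removal), and min–max normalize to [0, 1];
degenerate flat profiles return 0.5 everywhere with a flag. The deep-MUA
landmark QC looks for a local maximum of prominence ≥ 0.2 within ±0.1 mm of
the expected 0.6 mm depth; mice failing QC are flagged laminar-excluded but
remain usable for channel-averaged features. Depth 0 is the topmost
analyzed channel and increments by the 0.020 mm spacing — the convention
that makes the 45-channel span ≈ 0.9 mm and the quoted band edges
self-consistent; the superficial CSD band 0.20–0.36 mm is then channels
11–19 and the deep MUA band 0.50–0.64 mm channels 26–33. Somatotopic
selection scores candidate whisker pairs by mean |CSD| over channels ×
0–250 ms and breaks exact ties by lexical label order, flagged.

## The synthetic-data generator

The generator is a first-class, tested component that emulates the
statistical structure the analysis assumes; it is not a model of cortical
biophysics. Per mouse it draws:

* a latent-state timeline from a semi-Markov chain with geometric dwell
  times (scale `state_dwell_mean`, default 150 trials). Dwell means are
  state-dependent — persistent ×1, disengaged ×2.5, attentive ×2/3 — with
  entry weights rebalanced so prevalences are unchanged; the mean run
  length stays the harmonic mixture ≈ the configured scale. The longer
  disengaged (satiated) stretches and shorter, more frequent attentive
  episodes reflect the described session structure (abrupt late-session
  lick cessation; good performance emerging mid-session) and keep the
  50-trial smoothing from erasing short runs. Transition weights depend on
  the session phase `f` (disengagement ∝ f³ late) and the training day
  (attentive weight grows with day and peaks mid-session); the state is
  redrawn at each session start, emulating re-engagement on a new day;
* outcomes from state- and day-dependent response probabilities: persistent
  licks at 0.95 regardless of type, disengaged at 0.03, attentive follows a
  discrimination accuracy 0.5 + 0.48·(1 − exp(−2·learning_rate·(day−1)))
  (default `learning_rate` 0.3, chance on day 1, ≈0.95 by day 5);
* streams whose parameters are analytically calibrated so that the
  downstream extractors recover the configured per-state means:
  Poisson lick events (prestimulus rate = configured tendency, plus answer
  licking and a consummatory burst after hits), an encoder ramp integrating
  the configured trial speed (with an optional prestimulus running bump
  growing with training on attended trials), keypoint octagons with
  circumradius aperture/2 and small jitter, LFP as 1/f^α noise with
  α = −(configured slope) plus an asymmetric sink/source dipole whose
  channel-time mean over the stimulus window equals the configured evoked
  LFP, and white-noise high-rate epochs whose variance inverts the
  band-power relation (band sum = 20·s²/fs) with a Gaussian landmark burst
  at the configured depth (width 0.03 mm SD). The landmark burst is kept
  moderate relative to baseline deliberately: per-channel z-scoring
  saturates when a burst dwarfs the baseline, flattening the depth profile
  into a plateau and destroying localization.

Two pragmatic scope decisions follow the same logic as the analysis
windows: both the 20 kHz epochs *and* the LFP are synthesized only within
[−1.0, +0.25] s around each stimulus onset, since every analysis window
(prestimulus second, stimulus window, laminar epoch) lies inside that span
and continuous full-session 64-channel signals would serve no analysis at
desk scale. Lick events, the encoder trace and the eye keypoints are
continuous across the session. All randomness fans out deterministically
from a single seed per mouse via a label-hash (`fan_seed`), so bundles are
bit-reproducible and individual streams can be skipped without perturbing
the others.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: no spike waveforms or spike sorting, no
electromyographic lick artifacts in the LFP, no oscillatory (periodic)
spectral peaks on top of the aperiodic slope, no eye blinks or tracking
dropouts beyond the punishment exclusion, no whisker kinematics, no
cross-channel noise correlations, and state transitions that are sharper
than real behavioral drift. Benchmarks on this generator demonstrate that
the pipeline's machinery is correct and calibrated, not that the biological
effect sizes are realistic.

## Numerical choices and degenerate inputs

* Moving-mean edges: centered window truncated at session edges (no
  artificial boundary values, no cross-day leakage).
* Histogram bin edges: equal width over the observed range; the cutoff is
  the upper edge of bin 2, ties inclusive.
* All-identical lick rates: all trials low/no licking if the value is 0,
  otherwise an error with a diagnostic (a degenerate histogram means the
  input is not a lick-rate vector).
* ROC with an empty class: flagged `NA`, never silently 0.5.
* Asymptotic fit: multi-start over `k` ∈ {0.05, …, 5}; non-convergence or
  constant input → flagged result with `NA` parameters.
* z-scoring of all-constant channels: left at zero with a degeneracy flag.
* Quantile definition: R's type-7 (linear interpolation) sample quantile.
* Lick/interval membership: half-open `[start, end)` windows everywhere, so
  boundary events are counted exactly once.

## Problem sizes used in the checks

The packaged tests and the acceptance script run the full pipeline at
reduced probe sizes (3–4 channels, with landmark and dipole depths placed
inside the reduced span) and with iteration counts of 3–20 rather than 100,
sizes chosen so the whole suite completes on a laptop core in minutes while
every statistical property under test retains adequate power; the
full-scale defaults (64 channels, 100 iterations) are exercised on small
trial counts. Simulation-based checks (type-I calibration at 1,000 null
replicates, trend and interaction detection over 5–20 seeds, landmark
recovery over 20 seeds) state their replicate counts in the test code.

## Known limitations

* The tripartite labels inherit the hard 25% attentive budget of the
  quantile cutoff; mice whose true attentive prevalence is far from 25%
  will be mislabeled near the cutoff.
* The 50-trial smoothing blurs ~25 trials at every state-run boundary;
  state runs much shorter than the window are invisible by design (the
  analysis targets minutes-scale fluctuations, not single-trial switches).
* ANOVA error strata use blocks as units pooled across mice; mouse identity
  is not a random effect, matching the original analysis structure rather
  than a maximal mixed model.
* The laminar depth axis assumes the topmost analyzed channel sits at the
  cortical surface; no layer boundaries are assigned.
* Real acquisition formats (Intan, NWB) are not read; the bundle reader
  targets the package's own portable text layout, and is an extension
  point.
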