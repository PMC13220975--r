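# motistate

Motivation-state fluctuations and learning in head-fixed go/no-go training.

Mice trained on a whisker-based go/no-go task do not behave uniformly within
a session: they drift between stretches of indiscriminate licking, stretches
of task disengagement, and stretches of genuinely attentive discrimination.
`motistate` implements a complete analysis pipeline for this setting, aimed
at systems-neuroscience labs working with trial-based head-fixed behavior
and laminar silicon-probe recordings:

* **State labeling.** Whole-trial lick rates and binary correctness are
  smoothed with a 50-trial moving mean (independently per daily session),
  concatenated across days per mouse, and binarized — licking by the two
  lowest bins of a 100-bin histogram, correctness by the mouse's own 75th
  quantile. Merging the axes gives the tripartite trial categories:

  - *persistent*: moderate/high licking at chance performance,
  - *disengaged*: low/no licking,
  - *attentive*: good performance (at or above the quantile cutoff).

* **State prediction.** Eight "nonperformance" variables — prestimulus lick
  rate, whole-trial wheel speed, pupil diameter, eyelid aperture, the
  aperiodic power-spectrum slope (PSS, the slope of log10 power vs log10
  frequency over 1–100 Hz), evoked LFP, prestimulus multiunit (MUA)
  500–5,000 Hz band power, and evoked MUA — are fed to bagged ensembles of
  30 fully grown decision trees. Trials are shuffled in 25-trial blocks,
  split 1:1 into swapped train/held-out halves, and scored with one-vs-rest
  ROC curves pooled over groups of iterations. AUC as a function of the
  predictor-pool size (1–8 variables) is quantified by nonlinear
  least-squares fits of the asymptotic exponential `y = a − b·exp(−k·x)`,
  with a p-value for the rate `k`. Controls include cross-mouse transfer,
  row/full shuffling, predictor subsets, and GLM/multinomial-regression
  leave-one-predictor-out analyses with Friedman tests.

* **Training progression.** Trials are sorted into the eight retained
  state × outcome subcategories, mapped onto a normalized 99-block
  progression axis (early/mid/late stages of 33 blocks each), and their
  peristimulus motor patterns (lick rate, wheel speed, pupil, eyelid over
  [−1, +4] s in 80 bins) are compared across stages with two-way
  repeated-measures ANOVA and Tukey-protected post hocs.

* **Laminar electrophysiology.** Peristimulus current-source density
  (second spatial derivative of the LFP, z-scored, 5-channel/20-ms
  smoothing) and MUA power maps (4-ms spectrogram windows, 500-Hz bins,
  z-scored, 10-ms smoothing) over the 45 topmost channels (0.9 mm at 20 µm
  spacing) are reduced to normalized depth profiles (absolute response,
  0–100 ms average, 22-channel detrend, 0–1 scaling), with landmark QC at
  the ~0.6 mm deep-MUA feature, somatotopic whisker-pair selection, and
  depth-band statistics (superficial CSD 0.20–0.36 mm, deep MUA
  0.50–0.64 mm).

* **Synthetic data.** A first-class generator emulates multi-mouse training
  courses — constrained pseudorandom go/no-go sequences (no more than three
  consecutive repetitions), a semi-Markov latent-state timeline with
  ~150-trial dwell, session-phase and training-day biases, and all raw
  streams (lick events, wrapping 0–3.3 V wheel encoder, eye keypoint
  octagons at 20 frames/s, laminar LFP at 1,250 Hz, 20 kHz epochs) — so the
  entire pipeline is testable end to end with no animal data.

## Worked example

```r
library(motistate)

# one virtual mouse, short course, reduced 4-channel probe
cf <- mouse_config("demo", n_sessions = 2, trials_per_session = 120,
                   seed = 101, n_channels = 4,
                   landmark_depth_mm = 0.04, dipole_depth_mm = 0.02)
bundle <- gen_dataset(list(cf))

feats  <- trial_features(bundle)
labels <- label_states(feats)
table(labels$state)
#> persistent disengaged  attentive
#>        157         23         60

sm  <- smooth_features(feats)
run <- train_predict(sm[, nonperformance_vars()], labels$state, seed = 1)
sapply(pooled_roc(list(run), labels$state), `[[`, "auc")
#> persistent disengaged  attentive
#>  0.9179469  0.9931889  0.9433403
```

The state counts show the expected structure for an early-training mouse
(mostly persistent licking, a late-session disengaged stretch, attentive
stretches emerging); the one-vs-rest AUCs near 0.9+ show that the eight
nonperformance variables carry the state signal. Applying the full-shuffle
control (`control_predictions(..., mode = "full_shuffle")`) collapses these
AUCs to ≈ 0.5.

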