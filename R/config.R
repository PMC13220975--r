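# Configuration objects: per-mouse generator settings and the pipeline
# parameter registry. Every tunable that the analysis quotes a value for
# defaults to that value here.

#' Default state coupling of the eight nonperformance variables
#'
#' Each entry gives the per-state mean (persistent, disengaged, attentive),
#' the trial-to-trial spread (`sd`), and an additive per-session drift that
#' models gradual motor/physiologic change with training. Units follow the
#' feature definitions: licks (count in the 1 s prestimulus window), cm/s,
#' mm, dimensionless slope, microvolts, and arbitrary band-power units.
#'
#' The default means encode the qualitative structure the labels rest on:
#' near-zero licking and a steeper (more negative) aperiodic slope, smaller
#' pupil, droopier eyelid and weaker multiunit activity when disengaged;
#' strongest arousal and evoked responses when attentive.
#'
#' @return named list of coupling entries.
#' @export
default_feature_coupling <- function() {
  cp <- function(per, dis, att, sd, drift = 0) {
    list(mean = c(persistent = per, disengaged = dis, attentive = att),
         sd = sd, drift = drift)
  }
  list(
    prestim_lick_rate = cp(3.5, 0.05, 1.2, sd = 0,    drift = 0),
    wheel_speed       = cp(6.0, 0.5,  3.0, sd = 1.0,  drift = 0.10),
    pupil_diameter    = cp(1.1, 0.7,  1.3, sd = 0.05, drift = 0.01),
    eyelid_aperture   = cp(2.2, 1.4,  2.6, sd = 0.08, drift = 0),
    prestim_pss       = cp(-1.3, -2.0, -1.0, sd = 0.10, drift = -0.01),
    evoked_lfp        = cp(40, 15, 60, sd = 5,    drift = 1.0),
    prestim_mua_power = cp(2.0, 1.0, 3.0, sd = 0.15, drift = 0.04),
    evoked_mua        = cp(3.0, 1.3, 4.2, sd = 0.25, drift = 0.06)
  )
}

#' Generator configuration for one virtual mouse
#'
#' Defines the training schedule, latent-state dynamics, feature-state
#' coupling and probe geometry that the synthetic-data generator emulates.
#'
#' @param mouse_id character identifier.
#' @param n_sessions daily sessions (default 14; study range 12-14).
#' @param trials_per_session trials per daily session (default 500).
#' @param seed integer seed for this mouse's substreams.
#' @param learning_rate controls across-session growth of both attentive
#'   prevalence and attentive discrimination accuracy; 0 disables learning.
#' @param state_dwell_mean mean latent-state run length in trials.
#' @param feature_coupling see [default_feature_coupling()].
#' @param n_channels probe channel count (default 64).
#' @param spacing_mm inter-channel spacing in mm (default 0.020).
#' @param lfp_rate LFP sampling rate, Hz (default 1250).
#' @param raw_rate high-rate epoch sampling rate, Hz (default 20000).
#' @param encoder_rate wheel-encoder sampling rate, Hz (default 100; the
#'   encoder trace is a slow wrapping ramp, so a modest rate suffices).
#' @param frame_rate eye-video frame rate, frames/s (default 20).
#' @param wheel_circumference_cm wheel circumference for the 0-3.3 V
#'   encoder rescale (default 36, the stated rescale range).
#' @param dipole_depth_mm depth of the evoked LFP sink (default 0.28).
#' @param landmark_depth_mm depth of the deep multiunit landmark
#'   (default 0.6); must lie within the probe span.
#' @param landmark_width_mm Gaussian depth width (SD) of the landmark
#'   burst (default 0.03, a feature on the ~0.1-0.2 mm scale).
#' @param wheel_accel_gain amplitude (cm/s) of the prestimulus running
#'   bump that grows with training on attended trials; 0 disables it.
#' @param lfp_noise_sd background LFP standard deviation, microvolts.
#' @return object of class `mouse_config`.
#' @export
mouse_config <- function(mouse_id = "m1",
                         n_sessions = 14,
                         trials_per_session = 500,
                         seed = 1,
                         learning_rate = 0.3,
                         state_dwell_mean = 150,
                         feature_coupling = default_feature_coupling(),
                         n_channels = 64,
                         spacing_mm = 0.020,
                         lfp_rate = 1250,
                         raw_rate = 20000,
                         encoder_rate = 100,
                         frame_rate = 20,
                         wheel_circumference_cm = 36,
                         dipole_depth_mm = 0.28,
                         landmark_depth_mm = 0.6,
                         landmark_width_mm = 0.03,
                         wheel_accel_gain = 3,
                         lfp_noise_sd = 50) {
  if (n_sessions < 1) stopf("n_sessions must be >= 1")
  if (trials_per_session < 1) stopf("trials_per_session must be >= 1")
  if (state_dwell_mean < 1) stopf("state_dwell_mean must be >= 1")
  if (spacing_mm <= 0) stopf("spacing_mm must be > 0")
  span <- (n_channels - 1) * spacing_mm
  if (landmark_depth_mm < 0 || landmark_depth_mm > span)
    stopf("landmark_depth_mm (%g) outside probe span [0, %g] mm", landmark_depth_mm, span)
  if (dipole_depth_mm < 0 || dipole_depth_mm > span)
    stopf("dipole_depth_mm (%g) outside probe span [0, %g] mm", dipole_depth_mm, span)
  need <- nonperformance_vars()
  if (!all(need %in% names(feature_coupling)))
    stopf("feature_coupling missing: %s", paste(setdiff(need, names(feature_coupling)), collapse = ", "))
  structure(list(
    mouse_id = as.character(mouse_id), n_sessions = as.integer(n_sessions),
    trials_per_session = as.integer(trials_per_session), seed = as.integer(seed),
    learning_rate = learning_rate, state_dwell_mean = state_dwell_mean,
    feature_coupling = feature_coupling, n_channels = as.integer(n_channels),
    spacing_mm = spacing_mm, lfp_rate = lfp_rate, raw_rate = raw_rate,
    encoder_rate = encoder_rate, frame_rate = frame_rate,
    wheel_circumference_cm = wheel_circumference_cm,
    dipole_depth_mm = dipole_depth_mm, landmark_depth_mm = landmark_depth_mm,
    landmark_width_mm = landmark_width_mm,
    wheel_accel_gain = wheel_accel_gain, lfp_noise_sd = lfp_noise_sd
  ), class = "mouse_config")
}

#' Pipeline parameter registry
#'
#' Collects every analysis tunable with its default. Defaults reproduce the
#' quoted protocol values: 50-trial smoothing, 100 histogram bins, 75th
#' correctness quantile, 25-trial shuffle blocks, 30 bagged learners, 100
#' iterations per pool, 99 progression blocks, 80 peristimulus bins over
#' [-1, +4] s, 45 analyzed channels at 0.020 mm, CSD band 0.20-0.36 mm,
#' MUA band 0.50-0.64 mm, 0.6 mm landmark.
#'
#' @param ... overrides for any registry entry.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    smoothing_window = 50L,
    histogram_bins = 100L,
    correctness_quantile = 0.75,
    shuffle_block = 25L,
    n_trees = 30L,
    n_iterations = 100L,
    n_blocks = 99L,
    peristim_bins = 80L,
    peristim_window = c(-1, 4),
    prestim_dur = 1.0, stim_dur = 0.2, answer_dur = 1.8,
    iti_dur = 2.0, punished_iti_dur = 10.0,
    channels_analyzed = 45L,
    spacing_mm = 0.020,
    csd_band_mm = c(0.20, 0.36),
    mua_band_mm = c(0.50, 0.64),
    landmark_depth_mm = 0.6,
    landmark_tol_mm = 0.1,
    csd_spatial_smooth = 5L,
    csd_temporal_smooth_s = 0.020,
    mua_temporal_smooth_s = 0.010,
    detrend_channels = 22L,
    laminar_window = c(-0.05, 0.25),
    profile_window = c(0, 0.1),
    pss_band = c(1, 100),
    pss_bins = 100L,
    mua_band_hz = c(500, 5000),
    mua_bin_hz = 500
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stopf("unknown pipeline_config entries: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$smoothing_window < 1 || cfg$histogram_bins < 1 || cfg$n_blocks < 1)
    stopf("pipeline_config: window/bin/block counts must be >= 1")
  if (cfg$correctness_quantile <= 0 || cfg$correctness_quantile >= 1)
    stopf("pipeline_config: correctness_quantile must lie in (0, 1)")
  structure(cfg, class = "pipeline_config")
}
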