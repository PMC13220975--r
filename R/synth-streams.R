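# Continuous-stream synthesis for one session: lick events, wrapping wheel
# encoder, eye keypoint octagons, laminar LFP epochs and high-rate epochs.
#
# Signal calibration notes (used by the parameter-recovery tests):
#  * prestimulus lick counts are Poisson with the configured tendency as mean;
#  * encoder voltage integrates the configured trial speed, so the unwrapped
#    first difference recovers it;
#  * pupil/eyelid octagons have circumradius aperture/2 with top and bottom
#    vertices on the vertical axis, so the top-bottom hypotenuse equals the
#    configured aperture;
#  * LFP background is 1/f^alpha with alpha = -configured slope;
#  * white noise of variance s^2 at rate fs has one-sided density 2 s^2/fs,
#    so the 10-bin 500-5000 Hz band sum is 20 s^2/fs; baseline and evoked
#    multiunit variances are chosen by inverting that relation;
#  * the evoked dipole waveform/profile is scaled so its channel-and-time
#    mean over the 200 ms stimulus window equals the configured evoked LFP.

# epoch window (s, relative to stimulus onset) shared by LFP and raw epochs
EPOCH_WINDOW <- c(-1, 0.25)

epoch_times <- function(rate) {
  n <- floor((EPOCH_WINDOW[2] - EPOCH_WINDOW[1]) * rate) + 1L
  EPOCH_WINDOW[1] + (seq_len(n) - 1L) / rate
}

# Poisson event times within [t0, t1) at constant rate (events/s)
poisson_times <- function(t0, t1, rate) {
  if (t1 <= t0 || rate <= 0) return(numeric(0))
  k <- stats::rpois(1, rate * (t1 - t0))
  if (k == 0) return(numeric(0))
  sort(stats::runif(k, t0, t1))
}

# octagon keypoints: 8 vertices, circumradius r, first vertex at the top so
# the topmost/bottommost vertices sit on the vertical axis
octagon <- function(cx, cy, r, jitter_sd) {
  ang <- pi / 2 + (0:7) * pi / 4
  cbind(cx + r * cos(ang) + stats::rnorm(8, 0, jitter_sd),
        cy + r * sin(ang) + stats::rnorm(8, 0, jitter_sd))
}

# state-dependent baseline lick rates (Hz) outside the prestimulus window
BASE_LICK <- c(persistent = 3.0, disengaged = 0.02, attentive = 0.8)

#' Generate the continuous streams for one session
#'
#' Produces lick event times, the wrapping encoder voltage trace, per-frame
#' eye keypoints, and per-trial LFP and high-rate epochs covering
#' [-1, +0.25] s around each stimulus onset. All signal parameters are
#' driven by the per-trial tendency columns of the trial table.
#'
#' @param trials one session's rows of a [gen_trial_table()] (single `day`).
#' @param config the [mouse_config()] that produced the trial table.
#' @param seed integer seed for this session's substreams.
#' @param signals which streams to synthesize (default all). Skipping the
#'   neural streams (`"lfp"`, `"raw"`) makes behavior-only experiments
#'   cheap; skipped entries are NULL.
#' @return object of class `session_streams`: list with `day`, `lick_times`,
#'   `encoder` (`rate`, `voltage`), `keypoints` (`time`, `pupil`, `eyelid`;
#'   frame x vertex x (x, y) arrays in mm), `lfp_epochs` and `raw_epochs`
#'   (per-trial channels x samples matrices), `epoch_window`, `lfp_rate`,
#'   `raw_rate`, `t_end`.
#' @export
gen_session_streams <- function(trials, config, seed = NULL,
                                signals = c("licks", "encoder", "keypoints",
                                            "lfp", "raw")) {
  stopifnot(inherits(config, "mouse_config"))
  if (length(unique(trials$day)) != 1) stopf("gen_session_streams expects a single session")
  if (nrow(trials) != config$trials_per_session)
    stopf("trial count (%d) does not match config trials_per_session (%d)",
          nrow(trials), config$trials_per_session)
  need <- paste0("tend_", nonperformance_vars())
  if (!all(need %in% names(trials))) stopf("trial table lacks tendency columns")
  d <- trials$day[1]
  if (is.null(seed)) seed <- fan_seed(config$seed, "session", d)
  pc <- pipeline_config()
  nt <- nrow(trials)
  t_end <- trials$t_onset[nt] + trials$duration[nt]

  # each stream draws from its own deterministic substream so that
  # skipping one signal never perturbs another
  lick_times <- NULL; encoder <- NULL; keypoints <- NULL
  lfp_epochs <- NULL; raw_epochs <- NULL

  if ("licks" %in% signals) with_seed(fan_seed(seed, "licks"), {
    licks <- vector("list", nt)
    for (i in seq_len(nt)) {
      t0 <- trials$t_onset[i]; ts <- trials$t_stim[i]
      ev <- c(
        poisson_times(t0, ts, trials$tend_prestim_lick_rate[i]),
        poisson_times(ts, t0 + 5, BASE_LICK[[trials$latent_state[i]]])
      )
      responded <- trials$outcome[i] %in% c("hit", "false_alarm")
      if (responded) ev <- c(ev, poisson_times(ts + 0.15, ts + 1.0, 6))
      if (trials$outcome[i] == "hit")  # consummatory burst after the reward
        ev <- c(ev, poisson_times(ts + 0.3, ts + 1.3, 7))
      licks[[i]] <- ev
    }
    lick_times <- sort(unlist(licks))
  })

  if ("encoder" %in% signals) with_seed(fan_seed(seed, "encoder"), {
    er <- config$encoder_rate
    t_enc <- seq(0, t_end, by = 1 / er)
    speed <- numeric(length(t_enc))
    idx <- findInterval(t_enc, trials$t_onset)
    idx[idx < 1] <- 1
    speed <- trials$tend_wheel_speed[idx]
    if (config$wheel_accel_gain > 0 && config$n_sessions > 1) {
      # prestimulus running bump that grows with training on attended trials
      amp <- config$wheel_accel_gain * (d - 1) / (config$n_sessions - 1)
      attended <- trials$outcome %in% c("hit", "false_alarm")
      rel <- t_enc - trials$t_stim[idx]
      bump <- amp * exp(-((rel + 0.2)^2) / (2 * 0.15^2))
      speed <- speed + ifelse(attended[idx], bump, 0)
    }
    speed <- speed + stats::rnorm(length(speed), 0, 0.2)
    dist <- cumsum(speed / er)
    circ <- config$wheel_circumference_cm
    encoder <- list(rate = er, voltage = (dist %% circ) / circ * 3.3)
  })

  if ("keypoints" %in% signals) with_seed(fan_seed(seed, "keypoints"), {
    fr <- config$frame_rate
    t_frame <- seq(0, t_end, by = 1 / fr)
    fi <- findInterval(t_frame, trials$t_onset); fi[fi < 1] <- 1
    nf <- length(t_frame)
    pupil <- array(0, c(nf, 8, 2)); eyelid <- array(0, c(nf, 8, 2))
    for (k in seq_len(nf)) {
      pupil[k, , ] <- octagon(0, 0, trials$tend_pupil_diameter[fi[k]] / 2, 0.004)
      eyelid[k, , ] <- octagon(0, 0.2, trials$tend_eyelid_aperture[fi[k]] / 2, 0.004)
    }
    keypoints <- list(time = t_frame, pupil = pupil, eyelid = eyelid)
  })

  if ("lfp" %in% signals) with_seed(fan_seed(seed, "lfp"), {
    nch <- config$n_channels
    tl <- epoch_times(config$lfp_rate)
    stim_idx <- which(tl >= 0 & tl < pc$stim_dur)
    depth <- (seq_len(nch) - 1) * config$spacing_mm
    c0 <- which.min(abs(depth - config$dipole_depth_mm))
    # asymmetric sink with a weaker source above; channel-time mean over
    # the stimulus window normalized to 1 for amplitude calibration
    prof <- -exp(-((seq_len(nch) - c0)^2) / (2 * 3^2)) +
      0.4 * exp(-((seq_len(nch) - (c0 - 6))^2) / (2 * 3^2))
    wave <- ifelse(tl >= 0.01 & tl <= 0.09, sin(pi * (tl - 0.01) / 0.08), 0)
    dip_unit <- outer(prof, wave)
    dip_mean <- mean(dip_unit[, stim_idx])
    lfp_epochs <- vector("list", nt)
    for (i in seq_len(nt)) {
      alpha <- -trials$tend_prestim_pss[i]
      m <- matrix(0, nch, length(tl))
      for (ch in seq_len(nch))
        m[ch, ] <- colored_noise(length(tl), config$lfp_rate, alpha, config$lfp_noise_sd)
      if (abs(dip_mean) > 0)
        m <- m + (trials$tend_evoked_lfp[i] / dip_mean) * dip_unit
      lfp_epochs[[i]] <- m
    }
  })

  if ("raw" %in% signals) with_seed(fan_seed(seed, "raw"), {
    nch <- config$n_channels
    depth <- (seq_len(nch) - 1) * config$spacing_mm
    tr <- epoch_times(config$raw_rate)
    burst_idx <- which(tr >= 0 & tr < pc$stim_dur)
    wland <- exp(-((depth - config$landmark_depth_mm)^2) / (2 * config$landmark_width_mm^2))
    raw_epochs <- vector("list", nt)
    for (i in seq_len(nt)) {
      p_bg <- trials$tend_prestim_mua_power[i]
      sd_bg <- sqrt(p_bg * config$raw_rate / 20)
      m <- matrix(stats::rnorm(nch * length(tr), 0, sd_bg), nch, length(tr))
      extra <- max(0, trials$tend_evoked_mua[i] - p_bg)
      if (extra > 0) {
        var_e <- extra * config$raw_rate / 20 / mean(wland^2)
        m[, burst_idx] <- m[, burst_idx] +
          matrix(stats::rnorm(nch * length(burst_idx)), nch) * (sqrt(var_e) * wland)
      }
      raw_epochs[[i]] <- m
    }
  })

  structure(list(
    day = d, lick_times = lick_times, encoder = encoder,
    keypoints = keypoints,
    lfp_epochs = lfp_epochs, raw_epochs = raw_epochs,
    epoch_window = EPOCH_WINDOW, lfp_rate = config$lfp_rate,
    raw_rate = config$raw_rate, t_end = t_end
  ), class = "session_streams")
}

#' Generate a full multi-mouse dataset bundle
#'
#' Runs the trial-table and stream generators for every configured mouse
#' and packs the results with the generating ground truth. Deterministic
#' given the configs' seeds.
#'
#' @param mouse_configs list of [mouse_config()] objects.
#' @param streams logical; generate continuous streams (default TRUE). With
#'   FALSE only trial tables and truth are produced (cheap timelines for
#'   label-level experiments).
#' @param signals which streams to synthesize; see [gen_session_streams()].
#' @return object of class `motistate_bundle`: named list per mouse with
#'   `config`, `trials`, `streams` (list per session) and `truth`.
#' @export
gen_dataset <- function(mouse_configs, streams = TRUE,
                        signals = c("licks", "encoder", "keypoints",
                                    "lfp", "raw")) {
  if (length(mouse_configs) < 1) stopf("need at least one mouse_config")
  if (inherits(mouse_configs, "mouse_config")) mouse_configs <- list(mouse_configs)
  ids <- vapply(mouse_configs, function(cf) cf$mouse_id, "")
  if (anyDuplicated(ids)) stopf("duplicate mouse_id: %s", ids[duplicated(ids)][1])
  mice <- lapply(mouse_configs, function(cf) {
    tt <- gen_trial_table(cf)
    st <- NULL
    if (streams) {
      st <- lapply(seq_len(cf$n_sessions), function(d)
        gen_session_streams(tt[tt$day == d, ], cf, signals = signals))
    }
    truth <- list(
      latent_state = tt$latent_state,
      session_accuracy = attentive_accuracy(seq_len(cf$n_sessions), cf$learning_rate),
      state_means = lapply(cf$feature_coupling, function(x) x$mean),
      state_drift = vapply(cf$feature_coupling, function(x) x$drift, 0),
      landmark_depth_mm = cf$landmark_depth_mm,
      dipole_depth_mm = cf$dipole_depth_mm)
    list(config = cf, trials = tt, streams = st, truth = truth)
  })
  names(mice) <- ids
  structure(list(mice = mice, schema = "motistate-bundle/1"),
            class = "motistate_bundle")
}
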