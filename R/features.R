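# Per-trial performance and nonperformance metrics, plus per-session
# summaries with across-day trend tests.

#' Moving mean with shrinking edges
#'
#' Centered unweighted moving mean progressing in `step`-sample steps. The
#' window is truncated at the edges so the output has the same length as
#' the input and no out-of-range values are invented. Intended to be
#' applied independently within each session.
#'
#' @param x numeric vector.
#' @param window window length in samples (>= 1).
#' @param step step between output samples (default 1; larger steps return
#'   the smoothed values at `seq(1, length(x), step)`).
#' @return numeric vector (length `length(x)` when `step = 1`).
#' @export
moving_mean <- function(x, window, step = 1) {
  if (length(x) == 0) stopf("moving_mean: empty series")
  if (window < 1) stopf("moving_mean: window must be >= 1")
  n <- length(x)
  before <- floor((window - 1) / 2)
  after <- floor(window / 2)
  cs <- c(0, cumsum(x))
  lo <- pmax(1, seq_len(n) - before)
  hi <- pmin(n, seq_len(n) + after)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  if (step > 1) out <- out[seq(1, n, by = step)]
  out
}

#' Wheel speed from the wrapping encoder voltage
#'
#' Rescales 0-3.3 V to 0-`circumference` cm, unwraps across the wrap
#' boundary into an ever-ascending (or descending) distance curve, and
#' differentiates. Speed is signed: backward running is negative.
#'
#' @param voltage encoder trace in volts (within `[0, 3.3]`).
#' @param rate sampling rate of the trace (Hz).
#' @param circumference wheel circumference in cm (default 36).
#' @return numeric speed trace (cm/s), same length as `voltage` (the first
#'   sample repeats the first difference).
#' @export
wheel_speed <- function(voltage, rate, circumference = 36) {
  if (length(voltage) == 0) stopf("wheel_speed: empty trace")
  pos <- voltage / 3.3 * circumference
  d <- diff(pos)
  d[d > circumference / 2] <- d[d > circumference / 2] - circumference
  d[d < -circumference / 2] <- d[d < -circumference / 2] + circumference
  if (length(d) == 0) return(0)
  c(d[1], d) * rate
}

#' Aperture of one keypoint octagon
#'
#' The Euclidean distance (hypotenuse) between the topmost and bottommost
#' vertices of an 8-point keypoint set.
#'
#' @param pts vertices x (x, y) matrix.
#' @return scalar aperture.
#' @export
frame_aperture <- function(pts) {
  if (nrow(pts) < 2) stopf("eye_apertures: need at least 2 keypoints per octagon")
  top <- which.max(pts[, 2]); bot <- which.min(pts[, 2])
  sqrt(sum((pts[top, ] - pts[bot, ])^2))
}

#' Per-trial pupil diameter and eyelid aperture
#'
#' Aperture per frame is the Euclidean distance (hypotenuse) between the
#' topmost and bottommost vertices of the keypoint octagon; per-trial
#' values average the frames inside the trial, excluding frames in the
#' punishment extension of the intertrial interval. Trials with no valid
#' frames receive the session median, flagged in the `imputed` column.
#'
#' @param keypoints the `keypoints` element of a `session_streams`.
#' @param trials one session's trial rows.
#' @return data.frame with `pupil_diameter`, `eyelid_aperture`, `imputed`.
#' @export
eye_apertures <- function(keypoints, trials) {
  nf <- length(keypoints$time)
  ap_p <- vapply(seq_len(nf), function(k) frame_aperture(keypoints$pupil[k, , ]), 0)
  ap_e <- vapply(seq_len(nf), function(k) frame_aperture(keypoints$eyelid[k, , ]), 0)
  nt <- nrow(trials)
  pupil <- eyelid <- rep(NA_real_, nt)
  for (i in seq_len(nt)) {
    t0 <- trials$t_onset[i]
    t1 <- t0 + trials$duration[i]
    keep <- keypoints$time >= t0 & keypoints$time < t1
    if (trials$punished[i]) {
      # the punishment period is the intertrial extension beyond the
      # standard 5 s trial span
      keep <- keep & keypoints$time < t0 + 5
    }
    if (any(keep)) {
      pupil[i] <- mean(ap_p[keep]); eyelid[i] <- mean(ap_e[keep])
    }
  }
  imputed <- is.na(pupil) | is.na(eyelid)
  if (any(imputed)) {
    pupil[is.na(pupil)] <- stats::median(pupil, na.rm = TRUE)
    eyelid[is.na(eyelid)] <- stats::median(eyelid, na.rm = TRUE)
  }
  data.frame(pupil_diameter = pupil, eyelid_aperture = eyelid, imputed = imputed)
}

#' Whole-trial and prestimulus lick metrics
#'
#' Whole-trial rate counts licks in the 5 s trial span (half-open
#' `[onset, onset + 5)`; the punishment extension lies outside it) divided
#' by 5 s. The prestimulus metric counts licks in the 1 s before stimulus
#' onset.
#'
#' @param lick_times event times (s).
#' @param trials one session's trial rows.
#' @return data.frame with `whole_trial_lick_rate` (Hz), `prestim_lick_rate`.
#' @export
lick_metrics <- function(lick_times, trials) {
  nt <- nrow(trials)
  whole <- prestim <- numeric(nt)
  for (i in seq_len(nt)) {
    t0 <- trials$t_onset[i]; ts <- trials$t_stim[i]
    whole[i] <- sum(lick_times >= t0 & lick_times < t0 + 5) / 5
    prestim[i] <- sum(lick_times >= ts - 1 & lick_times < ts)
  }
  data.frame(whole_trial_lick_rate = whole, prestim_lick_rate = prestim)
}

#' Aperiodic power-spectrum slope of a prestimulus LFP epoch
#'
#' Per channel: Welch density (1 s window, 50% overlap), interpolated onto
#' logarithmically spaced bins spanning 1-100 Hz, log10-transformed and
#' fitted with a least-squares line against log10 frequency; the slopes
#' are averaged across channels.
#'
#' @param epoch channels x samples matrix (or vector for one channel).
#' @param fs sampling rate (Hz, default 1250).
#' @param band fitted frequency band (Hz).
#' @param n_bins number of log-spaced bins (default 100).
#' @param window_sec Welch window (default 1 s).
#' @return channel-averaged slope (dimensionless).
#' @export
prestim_pss <- function(epoch, fs = 1250, band = c(1, 100), n_bins = 100,
                        window_sec = 1) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  centers <- 10^seq(log10(band[1]), log10(band[2]), length.out = n_bins)
  lf <- log10(centers)
  slopes <- apply(epoch, 1, function(x) {
    w <- welch_psd(x, fs, window_sec = window_sec)
    lp <- log10(interp_psd(w$freq, w$psd, centers, log_axes = TRUE))
    unname(stats::coef(stats::lm.fit(cbind(1, lf), lp))[2])
  })
  mean(slopes)
}

#' Summed multiunit band power of a high-rate epoch
#'
#' Per channel: Welch density, interpolated onto linearly spaced bin
#' centers (`bin_hz` apart) spanning `band`, summed; averaged across
#' channels. Arbitrary power units.
#'
#' @param epoch channels x samples matrix (or vector).
#' @param fs sampling rate (Hz); must be at least twice the upper band edge.
#' @param band frequency band (Hz, default `c(500, 5000)`).
#' @param bin_hz bin spacing (default 500).
#' @param window_sec Welch window (default 0.5 s).
#' @return channel-averaged summed band power.
#' @export
mua_band_power <- function(epoch, fs = 20000, band = c(500, 5000),
                           bin_hz = 500, window_sec = 0.5) {
  if (fs < 2 * band[2]) stopf("mua_band_power: rate %g Hz below Nyquist for %g Hz", fs, band[2])
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  centers <- seq(band[1], band[2], by = bin_hz)
  mean(apply(epoch, 1, function(x) {
    w <- welch_psd(x, fs, window_sec = window_sec)
    sum(interp_psd(w$freq, w$psd, centers))
  }))
}

#' Evoked LFP and multiunit responses during the stimulus window
#'
#' Evoked LFP is the channel- and time-mean amplitude over the 200 ms
#' stimulus. Evoked multiunit activity is the summed 500-5,000 Hz band
#' power over the same window, computed with a 50 ms Welch window (the
#' default 0.5 s window cannot fit a 200 ms epoch).
#'
#' @param lfp_stim channels x samples LFP cut to the stimulus window.
#' @param raw_stim channels x samples high-rate epoch cut to the stimulus
#'   window (NULL yields `NA` evoked multiunit power, flagged upstream).
#' @param raw_rate high-rate sampling rate (Hz).
#' @return list with `evoked_lfp` and `evoked_mua`.
#' @export
evoked_responses <- function(lfp_stim, raw_stim, raw_rate = 20000) {
  ev_lfp <- mean(lfp_stim)
  ev_mua <- if (is.null(raw_stim)) NA_real_ else
    mua_band_power(raw_stim, fs = raw_rate, window_sec = 0.05)
  list(evoked_lfp = ev_lfp, evoked_mua = ev_mua)
}

#' Cut an epoch matrix to a peristimulus time window
#'
#' Epoch columns are assumed to span [-1.0, +0.25] s around stimulus onset
#' at the given sampling rate (the generator's epoch layout); the matrix is
#' cut to the half-open window `[window[1], window[2])`.
#'
#' @param m channels x samples matrix.
#' @param rate sampling rate (Hz).
#' @param window two-element window (s, relative to stimulus onset).
#' @return the cut matrix.
#' @export
cut_epoch <- function(m, rate, window) {
  tt <- epoch_times(rate)
  m[, tt >= window[1] & tt < window[2], drop = FALSE]
}

#' Build the per-trial feature table for a dataset bundle
#'
#' One row per trial in chronological order per mouse: whole-trial lick
#' rate and binary correctness plus the eight nonperformance variables.
#'
#' @param bundle a `motistate_bundle` with streams.
#' @param config a [pipeline_config()].
#' @return data.frame of class `trial_features` with identification
#'   columns (`mouse`, `day`, `trial`, `trial_type`, `outcome`,
#'   `latent_state`) followed by the feature columns.
#' @export
trial_features <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(bundle, "motistate_bundle"))
  out <- lapply(bundle$mice, function(m) {
    if (is.null(m$streams)) stopf("bundle has no streams for mouse %s", m$config$mouse_id)
    cf <- m$config
    per_day <- lapply(seq_len(cf$n_sessions), function(d) {
      session_features(m$trials[m$trials$day == d, ], m$streams[[d]], cf, config)
    })
    do.call(rbind, per_day)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trial_features", "data.frame")
  res
}

# feature extraction for one session's trials and streams
session_features <- function(tr, ss, cf, config) {
  lick <- lick_metrics(ss$lick_times, tr)
  speed <- wheel_speed(ss$encoder$voltage, ss$encoder$rate,
                       cf$wheel_circumference_cm)
  t_enc <- (seq_along(speed) - 1) / ss$encoder$rate
  wsp <- vapply(seq_len(nrow(tr)), function(i) {
    keep <- t_enc >= tr$t_onset[i] & t_enc < tr$t_onset[i] + 5
    mean(speed[keep])
  }, 0)
  eyes <- eye_apertures(ss$keypoints, tr)
  nt <- nrow(tr)
  pss <- lfp_ev <- muap <- mua_ev <- numeric(nt)
  for (i in seq_len(nt)) {
    lfp <- ss$lfp_epochs[[i]]; raw <- ss$raw_epochs[[i]]
    pss[i] <- prestim_pss(cut_epoch(lfp, ss$lfp_rate, c(-1, 0)),
                          fs = ss$lfp_rate, band = config$pss_band,
                          n_bins = config$pss_bins)
    muap[i] <- mua_band_power(cut_epoch(raw, ss$raw_rate, c(-1, 0)),
                              fs = ss$raw_rate, band = config$mua_band_hz,
                              bin_hz = config$mua_bin_hz)
    ev <- evoked_responses(cut_epoch(lfp, ss$lfp_rate, c(0, config$stim_dur)),
                           cut_epoch(raw, ss$raw_rate, c(0, config$stim_dur)),
                           raw_rate = ss$raw_rate)
    lfp_ev[i] <- ev$evoked_lfp; mua_ev[i] <- ev$evoked_mua
  }
  data.frame(
    mouse = tr$mouse, day = tr$day, trial = tr$trial,
    trial_type = tr$trial_type, outcome = tr$outcome,
    latent_state = tr$latent_state,
    whole_trial_lick_rate = lick$whole_trial_lick_rate,
    correctness = as.integer(tr$outcome %in% c("hit", "correct_rejection")),
    prestim_lick_rate = lick$prestim_lick_rate,
    wheel_speed = wsp,
    pupil_diameter = eyes$pupil_diameter,
    eyelid_aperture = eyes$eyelid_aperture,
    prestim_pss = pss, evoked_lfp = lfp_ev,
    prestim_mua_power = muap, evoked_mua = mua_ev,
    eye_imputed = eyes$imputed,
    stringsAsFactors = FALSE)
}

#' Simulate a mouse and extract its feature table session by session
#'
#' Generates one mouse's trial table, then synthesizes and analyzes each
#' session's streams in turn, discarding the raw signals after feature
#' extraction. Output is identical to [trial_features()] on the full
#' bundle, but peak memory stays at one session's streams — the practical
#' route for full-length training courses.
#'
#' @param cf a [mouse_config()].
#' @param config a [pipeline_config()].
#' @return a [trial_features()] table.
#' @export
simulate_features <- function(cf, config = pipeline_config()) {
  stopifnot(inherits(cf, "mouse_config"))
  tt <- gen_trial_table(cf)
  per_day <- lapply(seq_len(cf$n_sessions), function(d) {
    tr <- tt[tt$day == d, ]
    ss <- gen_session_streams(tr, cf)
    out <- session_features(tr, ss, cf, config)
    rm(ss); gc(FALSE)
    out
  })
  res <- do.call(rbind, per_day)
  rownames(res) <- NULL
  class(res) <- c("trial_features", "data.frame")
  res
}

#' Smooth feature columns with the session-wise moving mean
#'
#' Applies [moving_mean()] independently within each mouse x day to the
#' performance metrics and the eight nonperformance variables, matching
#' the smoothing used before state labeling and prediction.
#'
#' @param features a [trial_features()] table.
#' @param window smoothing window in trials (default 50).
#' @return the table with smoothed feature columns.
#' @export
smooth_features <- function(features, window = 50) {
  cols <- c("whole_trial_lick_rate", "correctness", nonperformance_vars())
  key <- interaction(features$mouse, features$day, drop = TRUE)
  for (cn in cols) {
    features[[cn]] <- stats::ave(features[[cn]], key,
                                 FUN = function(x) moving_mean(x, window))
  }
  features
}

#' Per-session summaries with across-day trend tests
#'
#' Peak correctness is the maximum of the 50-trial moving mean of binary
#' correctness within the session; other entries are session means. Trends
#' are Pearson correlations of the session values against training day,
#' aggregated across mice.
#'
#' @param features a [trial_features()] table (unsmoothed).
#' @param body_weights optional data.frame `mouse`, `day`, `body_weight`
#'   passed through to the summaries.
#' @param window smoothing window for peak correctness (default 50).
#' @return list with `summaries` (one row per mouse x day) and `trends`
#'   (metric, pearson_r, p_value), the latter NULL with a warning when
#'   only one session exists.
#' @export
session_summaries <- function(features, body_weights = NULL, window = 50) {
  sp <- split(features, interaction(features$mouse, features$day, drop = TRUE))
  summaries <- do.call(rbind, lapply(sp, function(s) {
    dur <- nrow(s) * 5  # informative licks live in the 5 s trial spans
    data.frame(
      mouse = s$mouse[1], day = s$day[1],
      peak_correctness = max(moving_mean(s$correctness, window)),
      mean_wheel_speed = mean(s$wheel_speed),
      mean_pss = mean(s$prestim_pss),
      mean_mua_power = mean(s$prestim_mua_power),
      lick_rate = sum(s$whole_trial_lick_rate * 5) / dur,
      mean_pupil_diameter = mean(s$pupil_diameter),
      mean_eyelid_aperture = mean(s$eyelid_aperture),
      stringsAsFactors = FALSE)
  }))
  rownames(summaries) <- NULL
  if (!is.null(body_weights))
    summaries <- merge(summaries, body_weights, by = c("mouse", "day"),
                       all.x = TRUE, sort = FALSE)
  trends <- NULL
  if (length(unique(summaries$day)) < 2) {
    warnf("single session: across-day trend tests skipped")
  } else {
    metrics <- setdiff(names(summaries), c("mouse", "day"))
    trends <- do.call(rbind, lapply(metrics, function(mn) {
      ok <- is.finite(summaries[[mn]])
      ct <- if (sum(ok) >= 3)
        tryCatch(stats::cor.test(summaries$day[ok], summaries[[mn]][ok]),
                 error = function(e) NULL) else NULL
      data.frame(metric = mn,
                 pearson_r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
                 p_value = if (is.null(ct)) NA_real_ else ct$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(summaries = summaries, trends = trends)
}
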