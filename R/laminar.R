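# Laminar electrophysiology: peristimulus CSD and multiunit-power
# channel x time maps, normalized depth profiles, landmark QC, somatotopy
# selection, depth-band statistics and laminar stage ANOVA.

# z-score rows of a matrix; all-constant rows are left at zero and flagged
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  degenerate <- sd == 0
  sd[degenerate] <- 1
  out <- (m - mu) / sd
  out[degenerate, ] <- 0
  attr(out, "degenerate") <- which(degenerate)
  out
}

smooth_rows <- function(m, window) {
  if (window <= 1) return(m)
  t(apply(m, 1, moving_mean, window = window))
}

smooth_cols <- function(m, window) {
  if (window <= 1) return(m)
  apply(m, 2, moving_mean, window = window)
}

#' Current-source-density map of a peristimulus LFP epoch
#'
#' Discrete second spatial derivative across channels per time sample
#' (edge channels replicate the nearest interior value so the channel
#' count is preserved), z-scored per channel over the epoch, then smoothed
#' across five channels and across 20 ms of samples.
#'
#' @param epoch channels x samples LFP matrix cut to the peristimulus
#'   window (use [cut_epoch()] with `c(-0.05, 0.25)`).
#' @param fs sampling rate (Hz, default 1250).
#' @param t_start time of the first column relative to stimulus onset
#'   (default -0.05 s).
#' @param spatial_smooth channel smoothing window (default 5).
#' @param temporal_smooth_s temporal smoothing window (default 0.020 s).
#' @return list of class `laminar_epoch`: `map` (channels x samples),
#'   `time` (s, relative to stimulus onset), `metric = "CSD"`,
#'   `degenerate_channels`.
#' @export
csd_map <- function(epoch, fs = 1250, t_start = -0.05,
                    spatial_smooth = 5, temporal_smooth_s = 0.020) {
  nch <- nrow(epoch)
  if (is.null(nch) || nch < 3) stopf("csd_map: need >= 3 channels")
  csd <- epoch[1:(nch - 2), , drop = FALSE] -
    2 * epoch[2:(nch - 1), , drop = FALSE] +
    epoch[3:nch, , drop = FALSE]
  csd <- rbind(csd[1, , drop = FALSE], csd, csd[nch - 2, , drop = FALSE])
  z <- zscore_rows(csd)
  deg <- attr(z, "degenerate")
  z <- smooth_rows(smooth_cols(z, spatial_smooth),
                   max(1L, round(temporal_smooth_s * fs)))
  structure(list(map = z, time = t_start + (seq_len(ncol(z)) - 1) / fs,
                 metric = "CSD", degenerate_channels = deg),
            class = "laminar_epoch")
}

#' Multiunit-power map of a peristimulus high-rate epoch
#'
#' Per channel: short-time summed 500-5,000 Hz band power (4 ms window,
#' 50% overlap, 500 Hz bins), z-scored per channel and temporally smoothed
#' over 10 ms; no spatial smoothing.
#'
#' @param epoch channels x samples high-rate matrix cut to the
#'   peristimulus window.
#' @param fs sampling rate (Hz, default 20000; must be >= 10 kHz).
#' @param t_start time of the first column relative to stimulus onset.
#' @param window_sec spectrogram window (default 0.004 s).
#' @param band,bin_hz band definition (defaults 500-5,000 Hz, 500 Hz bins).
#' @param temporal_smooth_s temporal smoothing window (default 0.010 s).
#' @return list of class `laminar_epoch`: `map` (channels x time steps),
#'   `time`, `metric = "MUA"`, `degenerate_channels`.
#' @export
mua_map <- function(epoch, fs = 20000, t_start = -0.05, window_sec = 0.004,
                    band = c(500, 5000), bin_hz = 500,
                    temporal_smooth_s = 0.010) {
  if (fs < 10000) stopf("mua_map: sampling rate must be >= 10 kHz")
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  curves <- apply(epoch, 1, function(x)
    stft_band_power(x, fs, window_sec = window_sec, band = band,
                    bin_hz = bin_hz)$power)
  m <- t(curves)
  tm <- stft_band_power(epoch[1, ], fs, window_sec = window_sec,
                        band = band, bin_hz = bin_hz)$time
  step <- if (length(tm) > 1) tm[2] - tm[1] else window_sec
  z <- zscore_rows(m)
  deg <- attr(z, "degenerate")
  z <- smooth_rows(z, max(1L, round(temporal_smooth_s / step)))
  structure(list(map = z, time = t_start + tm, metric = "MUA",
                 degenerate_channels = deg),
            class = "laminar_epoch")
}

#' Normalized laminar depth profile of a channel x time map
#'
#' Absolute values (sinks and sources contribute equally) averaged over
#' 0-100 ms post-stimulus per channel, detrended by subtracting a
#' centered 22-channel moving mean, then min-max normalized to `[0, 1]`.
#'
#' @param lam a `laminar_epoch` (or a plain channels x time matrix with a
#'   `time` argument).
#' @param time time axis when `lam` is a plain matrix.
#' @param window averaging window (default `c(0, 0.1)` s).
#' @param detrend_channels detrend window (default 22).
#' @param spacing_mm channel spacing for the depth axis (default 0.020).
#' @return list of class `laminar_profile`: `profile` (in `[0, 1]`),
#'   `depth_mm` (0 at the topmost channel), `metric`, `degenerate`.
#' @export
depth_profile <- function(lam, time = NULL, window = c(0, 0.1),
                          detrend_channels = 22, spacing_mm = 0.020) {
  if (inherits(lam, "laminar_epoch")) {
    m <- lam$map; time <- lam$time; metric <- lam$metric
  } else {
    m <- lam; metric <- NA_character_
    if (is.null(time)) stopf("depth_profile: time axis required for plain matrices")
  }
  keep <- time >= window[1] & time <= window[2]
  if (!any(keep)) stopf("depth_profile: map does not cover %g-%g s", window[1], window[2])
  raw <- rowMeans(abs(m[, keep, drop = FALSE]))
  det <- raw - moving_mean(raw, detrend_channels)
  rng <- range(det)
  if (diff(rng) == 0) {
    return(structure(list(profile = rep(0.5, length(det)),
                          depth_mm = (seq_along(det) - 1) * spacing_mm,
                          metric = metric, degenerate = TRUE),
                     class = "laminar_profile"))
  }
  structure(list(profile = (det - rng[1]) / diff(rng),
                 depth_mm = (seq_along(det) - 1) * spacing_mm,
                 metric = metric, degenerate = FALSE),
            class = "laminar_profile")
}

#' Deep multiunit landmark quality control
#'
#' Searches the profile for a local maximum of sufficient prominence
#' within `expected_depth +/- tolerance`. Mice failing QC are flagged
#' laminar-excluded (their channel-averaged features remain usable).
#'
#' @param profile a `laminar_profile` (or numeric vector with `depth_mm`).
#' @param depth_mm depth axis when `profile` is a plain vector.
#' @param expected_depth expected landmark depth (default 0.6 mm).
#' @param tolerance search half-width (default 0.1 mm).
#' @param prominence minimum height above the flanking minima on the 0-1
#'   profile scale (default 0.2).
#' @return list with `pass`, `detected_depth_mm` (NA on failure).
#' @export
mua_landmark_qc <- function(profile, depth_mm = NULL, expected_depth = 0.6,
                            tolerance = 0.1, prominence = 0.2) {
  if (inherits(profile, "laminar_profile")) {
    depth_mm <- profile$depth_mm; y <- profile$profile
  } else y <- profile
  n <- length(y)
  if (n < 3) return(list(pass = FALSE, detected_depth_mm = NA_real_))
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  peaks <- which(is_peak)
  prom <- vapply(peaks, function(i) {
    left <- min(y[1:i]); right <- min(y[i:n])
    y[i] - max(left, right)
  }, 0)
  good <- peaks[prom >= prominence &
                  abs(depth_mm[peaks] - expected_depth) <= tolerance]
  if (length(good) == 0) return(list(pass = FALSE, detected_depth_mm = NA_real_))
  best <- good[which.max(y[good])]
  list(pass = TRUE, detected_depth_mm = depth_mm[best])
}

#' Select the whisker pair with the maximum CSD response
#'
#' Scores each candidate pair by the mean absolute CSD over channels and
#' 0-250 ms post-stimulus; ties break by lexical pair label, flagged.
#'
#' @param responses named list of trial-averaged `laminar_epoch` objects
#'   (or plain matrices with a shared `time` axis), one per whisker pair.
#' @param time shared time axis for plain matrices.
#' @param window scoring window (default `c(0, 0.25)` s).
#' @return list with `pair`, `scores`, `tie`.
#' @export
somatotopy_select <- function(responses, time = NULL, window = c(0, 0.25)) {
  if (length(responses) < 1) stopf("somatotopy_select: no candidate pairs")
  scores <- vapply(responses, function(r) {
    if (inherits(r, "laminar_epoch")) {m <- r$map; tt <- r$time}
    else {m <- r; tt <- time}
    keep <- tt >= window[1] & tt <= window[2]
    mean(abs(m[, keep, drop = FALSE]))
  }, 0)
  if (all(scores == 0)) stopf("somatotopy_select: all responses are zero")
  best <- max(scores)
  winners <- sort(names(scores)[scores == best])
  list(pair = winners[1], scores = scores, tie = length(winners) > 1)
}

#' Channels whose depths fall inside a band
#'
#' Depth 0 sits at the topmost analyzed channel and increments by
#' `spacing_mm`; both band edges are inclusive.
#'
#' @param band two-element depth band (mm).
#' @param n_channels number of analyzed channels.
#' @param spacing_mm inter-channel spacing (default 0.020).
#' @return integer channel indices.
#' @export
band_channels <- function(band, n_channels, spacing_mm = 0.020) {
  depth <- (seq_len(n_channels) - 1) * spacing_mm
  if (band[1] > max(depth) || band[2] < 0)
    stopf("band %g-%g mm outside probe span", band[1], band[2])
  which(depth >= band[1] & depth <= band[2])
}

# Friedman post hocs on mean ranks (Nemenyi / Tukey range statistic)
friedman_posthoc <- function(m, alpha = 0.05) {
  n <- nrow(m); k <- ncol(m)
  rk <- t(apply(m, 1, rank))
  mr <- colMeans(rk)
  crit <- stats::qtukey(1 - alpha, k, Inf) / sqrt(2) * sqrt(k * (k + 1) / (6 * n))
  pairs <- utils::combn(colnames(m), 2)
  data.frame(a = pairs[1, ], b = pairs[2, ],
             diff_rank = abs(mr[pairs[1, ]] - mr[pairs[2, ]]),
             significant = abs(mr[pairs[1, ]] - mr[pairs[2, ]]) > crit,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Depth-band statistics across trial subcategories
#'
#' Averages each per-block profile over a depth band (superficial CSD
#' 0.20-0.36 mm or deep multiunit 0.50-0.64 mm), eliminating the laminar
#' dimension, then compares subcategories within each training stage with
#' a Friedman test (blocks as the repeated measure) and Tukey-protected
#' rank post hocs.
#'
#' @param band_means data.frame with columns `subcategory`, `stage`,
#'   `block` (1-based within stage) and `value` (the band mean per block);
#'   build values with [band_mean()].
#' @param alpha protection level (default 0.05).
#' @return list per stage: `friedman` (statistic, df, p) and `posthoc`
#'   (NULL unless the Friedman test is significant).
#' @export
depth_band_stats <- function(band_means, alpha = 0.05) {
  out <- list()
  for (st in unique(as.character(band_means$stage))) {
    d <- band_means[band_means$stage == st, ]
    wide <- stats::reshape(d[, c("block", "subcategory", "value")],
                           idvar = "block", timevar = "subcategory",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub("^value\\.", "", colnames(m))
    m <- m[stats::complete.cases(m), , drop = FALSE]
    ft <- stats::friedman.test(m)
    ph <- if (ft$p.value < alpha) friedman_posthoc(m, alpha) else NULL
    out[[st]] <- list(friedman = data.frame(statistic = unname(ft$statistic),
                                            df = unname(ft$parameter),
                                            p_value = ft$p.value),
                      posthoc = ph)
  }
  out
}

#' Band mean of a laminar profile
#'
#' @param profile a `laminar_profile` or numeric vector.
#' @param band depth band in mm.
#' @param spacing_mm channel spacing (default 0.020).
#' @return scalar mean over the band's channels.
#' @export
band_mean <- function(profile, band, spacing_mm = 0.020) {
  y <- if (inherits(profile, "laminar_profile")) profile$profile else profile
  mean(y[band_channels(band, length(y), spacing_mm)])
}

#' Laminar stage ANOVA with depth channels as repeated measures
#'
#' Identical machinery to [stage_anova()], with the 45 analyzed depth
#' channels as the repeated-measure axis and trial blocks as units.
#'
#' @param data data.frame with `unit`, `stage`, `bin` (channel) and
#'   `value` columns.
#' @param alpha protection level.
#' @param posthoc logical; see [stage_anova()].
#' @return an `anova_result`; see [stage_anova()].
#' @export
laminar_stage_anova <- function(data, alpha = 0.05, posthoc = TRUE)
  stage_anova(data, alpha, posthoc)

#' Per-block laminar profiles for one subcategory
#'
#' Computes CSD or multiunit maps for every trial of a subcategory,
#' averages the maps within progression blocks, and reduces each block
#' average to a normalized depth profile.
#'
#' @param bundle_mouse one mouse's entry of a `motistate_bundle`.
#' @param trial_idx chronological trial row numbers of one subcategory.
#' @param blocks a [progression_blocks()] built from `trial_idx`.
#' @param metric `"CSD"` or `"MUA"`.
#' @param channels_analyzed topmost channels to analyze (default 45,
#'   capped at the probe size).
#' @param window peristimulus window (default `c(-0.05, 0.25)` s).
#' @return list with `profiles` (blocks x channels matrix, empty blocks
#'   NA), `depth_mm`, `stage`.
#' @export
laminar_block_profiles <- function(bundle_mouse, trial_idx, blocks,
                                   metric = c("CSD", "MUA"),
                                   channels_analyzed = 45,
                                   window = c(-0.05, 0.25)) {
  metric <- match.arg(metric)
  tt <- bundle_mouse$trials
  cf <- bundle_mouse$config
  nch <- min(channels_analyzed, cf$n_channels)
  trial_map <- function(row) {
    d <- tt$day[row]; i <- tt$trial[row]
    sess <- bundle_mouse$streams[[d]]
    if (metric == "CSD") {
      ep <- cut_epoch(sess$lfp_epochs[[i]][seq_len(nch), , drop = FALSE],
                      sess$lfp_rate, window)
      csd_map(ep, fs = sess$lfp_rate, t_start = window[1])
    } else {
      ep <- cut_epoch(sess$raw_epochs[[i]][seq_len(nch), , drop = FALSE],
                      sess$raw_rate, window)
      mua_map(ep, fs = sess$raw_rate, t_start = window[1])
    }
  }
  nb <- length(blocks$blocks)
  profiles <- matrix(NA_real_, nb, nch)
  for (b in seq_len(nb)) {
    rows <- blocks$blocks[[b]]
    if (length(rows) == 0) next
    maps <- lapply(rows, trial_map)
    avg <- Reduce(`+`, lapply(maps, `[[`, "map")) / length(maps)
    pr <- depth_profile(avg, time = maps[[1]]$time, spacing_mm = cf$spacing_mm)
    profiles[b, ] <- pr$profile
  }
  list(profiles = profiles,
       depth_mm = (seq_len(nch) - 1) * cf$spacing_mm,
       stage = blocks$stage)
}
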