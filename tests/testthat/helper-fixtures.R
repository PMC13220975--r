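# Shared fixtures, generated once per test run and cached. All fixtures are
# built in code from seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small reduced-probe config: 4 channels span 0.06 mm, so landmark and
# dipole depths are placed inside that span
small_config <- function(seed = 101, ...) {
  mouse_config("m1", n_sessions = 2, trials_per_session = 120, seed = seed,
               n_channels = 4, landmark_depth_mm = 0.04,
               dipole_depth_mm = 0.02, wheel_accel_gain = 0, ...)
}

fx_bundle <- function() fixture("bundle", function() gen_dataset(list(small_config())))
fx_features <- function() fixture("features", function() trial_features(fx_bundle()))

# idealized feature table straight from the latent tendencies: exercises the
# classifier layer without the stream-synthesis cost
fx_pred <- function() fixture("pred", function() {
  cf <- mouse_config("p1", n_sessions = 7, trials_per_session = 500, seed = 11,
                     n_channels = 4, landmark_depth_mm = 0.04,
                     dipole_depth_mm = 0.02)
  tl <- gen_state_timeline(cf)
  x <- tl[, paste0("tend_", nonperformance_vars())]
  colnames(x) <- nonperformance_vars()
  set.seed(99)
  for (j in seq_len(ncol(x))) x[[j]] <- x[[j]] + rnorm(nrow(x), 0, 0.05 * max(sd(x[[j]]), 1e-3))
  list(x = x, y = factor(tl$state, levels = c("persistent", "disengaged", "attentive")))
})

# behavior-only features (licks + outcomes) for labeling experiments at the
# full default scale of one mouse
behavior_features <- function(seed) {
  cf <- mouse_config(paste0("bm", seed), seed = seed, n_channels = 4,
                     landmark_depth_mm = 0.04, dipole_depth_mm = 0.02)
  b <- gen_dataset(list(cf), signals = "licks")
  tt <- b$mice[[1]]$trials
  lick <- do.call(rbind, lapply(seq_len(cf$n_sessions), function(d)
    lick_metrics(b$mice[[1]]$streams[[d]]$lick_times, tt[tt$day == d, ])))
  list(features = data.frame(
    mouse = tt$mouse, day = tt$day, trial = tt$trial,
    whole_trial_lick_rate = lick$whole_trial_lick_rate,
    correctness = as.integer(tt$outcome %in% c("hit", "correct_rejection"))),
    truth = tt$latent_state)
}

cohen_kappa <- function(a, b) {
  lv <- union(unique(a), unique(b))
  tab <- table(factor(a, lv), factor(b, lv))
  po <- sum(diag(tab)) / sum(tab)
  pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
  (po - pe) / (1 - pe)
}

# independent brute-force oracles ------------------------------------------

oracle_moving_mean <- function(x, window) {
  n <- length(x)
  before <- floor((window - 1) / 2); after <- floor(window / 2)
  sapply(seq_len(n), function(i) mean(x[max(1, i - before):min(n, i + after)]))
}

# AUC by exhaustive pairwise comparison (Mann-Whitney with ties at 1/2)
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# mixed-design ANOVA F statistics by direct sums-of-squares decomposition
oracle_mixed_anova <- function(d) {
  d$unit <- factor(d$unit); d$stage <- factor(d$stage); d$bin <- factor(d$bin)
  gm <- mean(d$value)
  a <- nlevels(d$stage); b <- nlevels(d$bin)
  units_per <- table(d$stage) / b
  ss_stage <- sum(tapply(d$value, d$stage, function(v) length(v) * (mean(v) - gm)^2))
  unit_means <- tapply(d$value, d$unit, mean)
  unit_stage <- tapply(as.character(d$stage), d$unit, `[`, 1)
  stage_means <- tapply(d$value, d$stage, mean)
  ss_units <- b * sum((unit_means - stage_means[unit_stage])^2)
  ss_bin <- sum(tapply(d$value, d$bin, function(v) length(v) * (mean(v) - gm)^2))
  cell <- tapply(d$value, list(d$stage, d$bin), mean)
  n_cell <- tapply(d$value, list(d$stage, d$bin), length)
  ss_int <- sum(n_cell * (cell - outer(stage_means - gm, tapply(d$value, d$bin, mean) - gm, `+`) - gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_res <- ss_tot - ss_stage - ss_units - ss_bin - ss_int
  df_stage <- a - 1
  df_units <- nlevels(d$unit) - a
  df_bin <- b - 1
  df_int <- (a - 1) * (b - 1)
  df_res <- df_units * (b - 1)
  list(F_stage = (ss_stage / df_stage) / (ss_units / df_units),
       F_bin = (ss_bin / df_bin) / (ss_res / df_res),
       F_int = (ss_int / df_int) / (ss_res / df_res))
}

# summed band power by direct DFT (explicit trigonometric sums, no fft)
oracle_band_power <- function(x, fs, window_sec, band = c(500, 5000), bin_hz = 500) {
  nw <- round(window_sec * fs)
  hop <- as.integer(round(nw / 2))
  starts <- seq(1L, length(x) - nw + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nw - 1)) / (nw - 1))
  half <- floor(nw / 2)
  freq <- (1:half) * fs / nw
  tsamp <- 0:(nw - 1)
  centers <- seq(band[1], band[2], by = bin_hz)
  pow <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- vapply(seq_len(half), function(k) {
      re <- sum(seg * cos(-2 * pi * k * tsamp / nw))
      im <- sum(seg * sin(-2 * pi * k * tsamp / nw))
      2 * (re^2 + im^2) / (fs * sum(w^2))
    }, 0)
    if (nw %% 2 == 0) p[half] <- p[half] / 2
    pow[i] <- sum(approx(freq, p, xout = centers, rule = 2)$y)
  }
  list(power = pow)
}
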