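# Feature extraction: smoothing, wheel, eye, licks, spectral estimators,
# evoked responses, end-to-end parameter recovery and session summaries.

test_that("moving mean matches the sliding-window oracle", {
  expect_equal(moving_mean(c(3, 1, 4, 1, 5), 1), c(3, 1, 4, 1, 5))
  expect_equal(moving_mean(rep(7, 20), 6), rep(7, 20))
  expect_equal(moving_mean(0:9, 3), oracle_moving_mean(0:9, 3))
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(5:80, 1))
    w <- sample(1:60, 1)
    expect_equal(moving_mean(x, w), oracle_moving_mean(x, w))
  }
  expect_error(moving_mean(1:5, 0), "window")
  expect_error(moving_mean(numeric(0), 3), "empty")
})

test_that("wheel speed unwraps the encoder and preserves sign", {
  rate <- 100
  expect_equal(wheel_speed(rep(1.1, 50), rate), rep(0, 50))
  # wheel turning exactly twice per second: 72 cm/s
  t <- seq(0, 2, by = 1 / rate)
  dist <- 72 * t
  v <- (dist %% 36) / 36 * 3.3
  sp <- wheel_speed(v, rate)
  expect_equal(sp, rep(72, length(sp)), tolerance = 1e-9)
  # backward running is the negative of forward
  vb <- ((-dist) %% 36) / 36 * 3.3
  expect_equal(wheel_speed(vb, rate), -sp, tolerance = 1e-9)
  # constant-speed recovery within 1%
  dist2 <- 23.4 * t
  sp2 <- wheel_speed((dist2 %% 36) / 36 * 3.3, rate)
  expect_lt(max(abs(sp2 - 23.4) / 23.4), 0.01)
  expect_error(wheel_speed(numeric(0), rate), "empty")
})

test_that("eye apertures use the top-bottom hypotenuse and skip punishment", {
  # regular octagon of circumradius r: aperture 2r
  ang <- pi / 2 + (0:7) * pi / 4
  oct1 <- cbind(2.5 * cos(ang), 2.5 * sin(ang))
  expect_equal(frame_aperture(oct1), 5)
  # hand-computed hypotenuse between (0.3, 1.0) and (0.0, -0.5)
  pts <- rbind(c(0.3, 1.0), c(0.1, 0.2), c(0.0, -0.5), c(-0.1, 0.1))
  expect_equal(frame_aperture(pts), sqrt(2.34))
  expect_error(frame_aperture(rbind(c(0, 0))), "2 keypoints")
  # frames inside the punishment extension are excluded; a trial left with
  # no frames is imputed from the session median and flagged
  trials <- data.frame(t_onset = c(0, 13), t_stim = c(1, 14),
                       duration = c(13, 5), punished = c(TRUE, FALSE))
  kp_t <- c(7, 8, 9, 14, 15)  # trial 1 frames all in [5, 13) punishment
  mk <- function(r) {
    arr <- array(0, c(length(kp_t), 8, 2))
    for (k in seq_along(kp_t)) arr[k, , ] <- cbind(r[k] * cos(ang), r[k] * sin(ang))
    arr
  }
  kp <- list(time = kp_t, pupil = mk(rep(1, 5)), eyelid = mk(rep(2, 5)))
  res <- eye_apertures(kp, trials)
  expect_true(res$imputed[1])
  expect_false(res$imputed[2])
  expect_equal(res$pupil_diameter[2], 2)
  expect_equal(res$pupil_diameter[1], res$pupil_diameter[2])  # session median
})

test_that("lick metrics use half-open 5 s windows", {
  trials <- data.frame(t_onset = c(0, 5), t_stim = c(1, 6),
                       duration = c(5, 5), punished = FALSE)
  expect_equal(lick_metrics(numeric(0), trials)$whole_trial_lick_rate, c(0, 0))
  # 10 licks inside one 5 s trial: 2 Hz
  lm1 <- lick_metrics(seq(0.2, 4.7, length.out = 10), trials)
  expect_equal(lm1$whole_trial_lick_rate, c(2, 0))
  # boundary lick at exactly t = 5 belongs to the second trial only
  lm2 <- lick_metrics(c(4.999, 5.0), trials)
  expect_equal(lm2$whole_trial_lick_rate * 5, c(1, 1))
  # prestimulus window is [stim - 1, stim)
  lm3 <- lick_metrics(c(0.0, 0.5, 0.9999, 1.0), trials)
  expect_equal(lm3$prestim_lick_rate, c(3, 0))
  # brute-force interval membership on random event times
  set.seed(7)
  ev <- runif(200, 0, 10)
  lm4 <- lick_metrics(ev, trials)
  expect_equal(lm4$whole_trial_lick_rate * 5,
               c(sum(ev >= 0 & ev < 5), sum(ev >= 5 & ev < 10)))
})

test_that("the power-spectrum slope recovers synthesized exponents", {
  set.seed(21)
  white <- mean(replicate(50, prestim_pss(colored_noise(1250, 1250, 0, 5), fs = 1250)))
  expect_lt(abs(white), 0.15)
  pink2 <- mean(replicate(50, prestim_pss(colored_noise(1250, 1250, 2, 5), fs = 1250)))
  expect_lt(abs(pink2 + 2), 0.3)
  # amplitude scaling leaves the slope unchanged
  x <- colored_noise(1250, 1250, 1, 3)
  expect_equal(prestim_pss(x, 1250), prestim_pss(7.3 * x, 1250), tolerance = 1e-10)
  expect_error(prestim_pss(rnorm(500), fs = 1250), "shorter")
})

test_that("multiunit band power scales like a power and rejects low rates", {
  expect_equal(mua_band_power(rep(0, 20000), fs = 20000), 0)
  set.seed(3)
  x <- rnorm(20000)
  expect_equal(mua_band_power(2 * x, fs = 20000),
               4 * mua_band_power(x, fs = 20000), tolerance = 1e-10)
  # noise band-limited below 400 Hz carries almost no 500-5,000 Hz power
  lp <- colored_noise(20000, 20000, 0, 1)
  X <- fft(lp)
  f <- (seq_along(X) - 1) * 20000 / length(X)
  X[f > 400 & f < 20000 - 400] <- 0
  lp <- Re(fft(X, inverse = TRUE)) / length(X)
  broad <- mua_band_power(x, fs = 20000)
  expect_lt(mua_band_power(lp, fs = 20000), 0.01 * broad)
  expect_error(mua_band_power(x, fs = 8000), "Nyquist")
})

test_that("evoked responses reduce to channel-time means", {
  expect_equal(evoked_responses(matrix(4.2, 1, 1), NULL)$evoked_lfp, 4.2)
  # doubling the dipole amplitude increases the evoked LFP monotonically
  base <- matrix(rnorm(4 * 250, sd = 0.1), 4)
  dip <- outer(c(1, -0.5, 0.2, 0.1), sin(pi * seq_len(250) / 250))
  e1 <- evoked_responses(base + 5 * dip, NULL)$evoked_lfp
  e2 <- evoked_responses(base + 10 * dip, NULL)$evoked_lfp
  expect_gt(abs(e2), abs(e1))
})

test_that("feature extraction recovers the configured state means", {
  f <- fx_features()
  cp <- small_config()$feature_coupling
  expect_equal(nrow(f), 240)
  expect_true(all(nonperformance_vars() %in% names(f)))
  expect_true(all(f$correctness %in% 0:1))
  expect_true(all(f$whole_trial_lick_rate >= 0))
  zs <- c()
  for (v in nonperformance_vars()) {
    expd <- cp[[v]]$mean[f$latent_state] + cp[[v]]$drift * (f$day - 1)
    for (st in unique(f$latent_state)) {
      k <- f$latent_state == st
      if (sum(k) < 10) next
      zs <- c(zs, (mean(f[[v]][k]) - mean(expd[k])) /
                (sd(f[[v]][k]) / sqrt(sum(k))))
    }
  }
  # each group mean within sampling error of its target: all below 3 SE and
  # the expected ~95% share below 2 SE
  expect_lt(max(abs(zs)), 3)
  expect_gte(mean(abs(zs) < 2), 0.85)
})

test_that("session summaries report peak correctness and day trends", {
  f <- fx_features()
  res <- session_summaries(f)
  expect_equal(nrow(res$summaries), 2)
  expect_true(all(res$summaries$peak_correctness >= 0 &
                    res$summaries$peak_correctness <= 1))
  # a session of all-correct trials peaks at 1
  f1 <- f[f$day == 1, ]
  f1$correctness <- 1
  expect_warning(r1 <- session_summaries(f1), "single session")
  expect_equal(r1$summaries$peak_correctness, 1)
  expect_null(r1$trends)
  # with learning, the correctness trend across days (aggregated over a
  # cohort of mice, as the summary analysis prescribes) is positive and
  # significant in most replicate cohorts
  sig <- vapply(1:5, function(r) {
    sm <- do.call(rbind, lapply(1:3, function(m) {
      bf <- behavior_features(r * 100 + m)$features
      do.call(rbind, lapply(split(bf, bf$day), function(d)
        data.frame(day = d$day[1], peak = max(moving_mean(d$correctness, 50)))))
    }))
    ct <- cor.test(sm$day, sm$peak)
    ct$estimate > 0 && ct$p.value < 0.05
  }, NA)
  expect_gte(sum(sig), 4)
})
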