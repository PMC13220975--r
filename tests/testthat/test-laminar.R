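# Laminar maps and profiles: CSD finite differences, multiunit spectrogram
# power, depth profiles, landmark QC, somatotopy and depth-band statistics.

test_that("the CSD of a depth-affine potential vanishes at interior channels", {
  nch <- 10; ns <- 200
  epoch <- outer(seq_len(nch), rep(1, ns)) * 3.7 + 2  # linear in depth
  cm <- csd_map(epoch, fs = 1250)
  expect_true(all(cm$map == 0))
  expect_equal(cm$degenerate_channels, 1:nch)
  expect_error(csd_map(epoch[1:2, ]), "3 channels")
})

test_that("a channel impulse produces the +1 -2 +1 second-difference pattern", {
  nch <- 9; ns <- 50
  epoch <- matrix(0, nch, ns)
  epoch[5, 25] <- 1
  # undo the z-scoring/smoothing wrappers by checking the raw map with
  # minimal smoothing: z-scoring preserves the sign pattern per channel
  cm <- csd_map(epoch, fs = 1250, spatial_smooth = 1, temporal_smooth_s = 0)
  expect_gt(cm$map[4, 25], 0)
  expect_lt(cm$map[5, 25], 0)
  expect_gt(cm$map[6, 25], 0)
  # raw second difference is exactly (+1, -2, +1) before normalization
  raw <- epoch[3:nch - 2, ] - 2 * epoch[3:nch - 1, ] + epoch[3:nch, ]
  expect_equal(raw[c(3, 4, 5), 25], c(1, -2, 1))
  # non-degenerate z-scored rows have mean 0 and unit variance
  set.seed(4)
  cm2 <- csd_map(matrix(rnorm(10 * 200), 10), fs = 1250,
                 spatial_smooth = 1, temporal_smooth_s = 0)
  expect_lt(max(abs(rowMeans(cm2$map))), 1e-10)
  expect_equal(apply(cm2$map, 1, sd), rep(1, 10), tolerance = 1e-10)
})

test_that("multiunit maps localize an injected high-frequency burst", {
  set.seed(9)
  nch <- 32; fs <- 20000
  ns <- round(0.3 * fs)
  tt <- (seq_len(ns) - 1) / fs - 0.05
  epoch <- matrix(rnorm(nch * ns, sd = 0.5), nch, ns)
  burst <- tt >= 0.015 & tt <= 0.025
  epoch[30, burst] <- epoch[30, burst] + 8 * sin(2 * pi * 2000 * tt[burst])
  mm <- mua_map(epoch, fs = fs)
  peak <- which(mm$map == max(mm$map), arr.ind = TRUE)
  expect_equal(unname(peak[1, 1]), 30)
  expect_lt(abs(mm$time[peak[1, 2]] - 0.020), 0.01)
  # stationary noise: z-scored rows center on zero
  mm0 <- mua_map(matrix(rnorm(4 * ns), 4, ns), fs = fs)
  expect_lt(max(abs(rowMeans(mm0$map))), 0.05)
  expect_error(mua_map(epoch, fs = 8000), "10 kHz")
})

test_that("summed band power matches the direct DFT oracle within 1%", {
  set.seed(10)
  x <- rnorm(4000)
  mine <- stft_band_power(x, fs = 20000, window_sec = 0.004)
  orac <- oracle_band_power(x, fs = 20000, window_sec = 0.004)
  expect_equal(mine$power, orac$power, tolerance = 1e-6)
  # energy bookkeeping: band power of white noise scales with variance
  pw <- vapply(c(1, 2, 3), function(s) {
    set.seed(20)
    mean(stft_band_power(rnorm(20000, sd = s), fs = 20000, window_sec = 0.5)$power)
  }, 0)
  expect_equal(pw / pw[1], c(1, 4, 9), tolerance = 0.05)
})

test_that("depth profiles normalize, localize bumps and ignore broad trends", {
  nch <- 45; ns <- 150
  tt <- (seq_len(ns) - 1) / 1250 - 0.05
  bump <- exp(-((seq_len(nch) - 20)^2) / (2 * 2^2))
  m <- outer(bump, as.numeric(tt >= 0 & tt <= 0.1))
  pr <- depth_profile(m, time = tt)
  expect_equal(min(pr$profile), 0)
  expect_equal(max(pr$profile), 1)
  expect_lt(abs(which.max(pr$profile) - 20), 2)
  # an across-depth linear trend wider than the detrend window cancels
  m2 <- m + outer(seq_len(nch) * 0.05, rep(1, ns))
  pr2 <- depth_profile(abs(m2), time = tt)
  expect_lt(abs(which.max(pr2$profile) - 20), 2)
  # sign flip of the map leaves the profile unchanged (absolute magnitudes)
  expect_equal(depth_profile(-m, time = tt)$profile, pr$profile)
  # constant map degenerates to the flagged 0.5 profile
  pr0 <- depth_profile(matrix(1, nch, ns), time = tt)
  expect_true(pr0$degenerate)
  expect_true(all(pr0$profile == 0.5))
})

test_that("landmark QC accepts on-target bumps and rejects the rest", {
  depth <- (0:44) * 0.020
  on <- exp(-((depth - 0.60)^2) / (2 * 0.05^2))
  qc <- mua_landmark_qc(on, depth)
  expect_true(qc$pass)
  expect_lt(abs(qc$detected_depth_mm - 0.6), 0.06)
  expect_false(mua_landmark_qc(rep(0.4, 45), depth)$pass)
  off <- exp(-((depth - 0.10)^2) / (2 * 0.05^2))
  expect_false(mua_landmark_qc(off, depth)$pass)
})

test_that("somatotopy selection maximizes the mean absolute CSD", {
  tt <- seq(-0.05, 0.25, by = 1 / 1250)
  base <- outer(exp(-((1:20 - 10)^2) / 8), as.numeric(tt > 0 & tt < 0.1))
  resp <- list(D = base, C = 2 * base, E = 0.5 * base)
  sel <- somatotopy_select(resp, time = tt)
  expect_equal(sel$pair, "C")
  expect_false(sel$tie)
  expect_equal(somatotopy_select(list(only = base), time = tt)$pair, "only")
  tie <- somatotopy_select(list(b = base, a = base), time = tt)
  expect_equal(tie$pair, "a")  # lexical tie-break
  expect_true(tie$tie)
  expect_error(somatotopy_select(list(a = 0 * base), time = tt), "zero")
})

test_that("depth bands map to the stated channel indices and average values", {
  # 0.20-0.36 mm at 0.020 mm spacing, depth 0 at channel 1: channels 11-19
  expect_equal(band_channels(c(0.20, 0.36), 45), 11:19)
  expect_equal(band_channels(c(0.50, 0.64), 45), 26:33)
  expect_error(band_channels(c(2, 3), 45), "outside")
  expect_equal(band_mean(rep(0.7, 45), c(0.20, 0.36)), 0.7)
  # Friedman across subcategories within a stage, with rank post hocs
  set.seed(15)
  bm <- expand.grid(block = 1:20, subcategory = paste0("s", 1:4),
                    stage = "early")
  bm$value <- rnorm(nrow(bm)) + (bm$subcategory == "s3") * 2
  st <- depth_band_stats(bm)
  expect_lt(st$early$friedman$p_value, 0.01)
  expect_true(any(st$early$posthoc$significant))
})

test_that("laminar profiles from the generator localize landmark and dipole", {
  cf <- mouse_config("m1", n_sessions = 1, trials_per_session = 40, seed = 77,
                     n_channels = 64)
  b <- gen_dataset(list(cf), signals = c("licks", "lfp", "raw"))
  bm <- b$mice$m1
  idx <- 1:40
  bl <- progression_blocks(idx, 4)
  mp <- laminar_block_profiles(bm, idx, bl, "MUA", channels_analyzed = 45)
  prof <- colMeans(mp$profiles)
  qc <- mua_landmark_qc(prof, mp$depth_mm, expected_depth = 0.6)
  expect_true(qc$pass)
  expect_lt(abs(qc$detected_depth_mm - 0.6), 0.04)
  cpf <- laminar_block_profiles(bm, idx, bl, "CSD", channels_analyzed = 45)
  prof2 <- colMeans(cpf$profiles)
  expect_lt(abs(mp$depth_mm[which.max(prof2)] - cf$dipole_depth_mm), 0.08)
})

test_that("attenuating the evoked dipole with training drives a laminar interaction", {
  hits <- vapply(1:5, function(s) {
    cp <- default_feature_coupling()
    cp$evoked_lfp$mean[] <- c(80, 25, 90)
    cp$evoked_lfp$drift <- -13
    cf <- mouse_config("m1", n_sessions = 6, trials_per_session = 80,
                       seed = s + 300, n_channels = 16, feature_coupling = cp,
                       landmark_depth_mm = 0.28, dipole_depth_mm = 0.10)
    b <- gen_dataset(list(cf), signals = c("licks", "lfp"))
    bm <- b$mice$m1
    tt <- bm$trials
    sc <- sort_subcategories(tt$latent_state, tt$outcome)
    idx <- sc$index[["persistent.hit"]]
    bl <- progression_blocks(idx, 12)
    lp <- laminar_block_profiles(bm, idx, bl, "CSD", channels_analyzed = 16)
    ok <- which(stats::complete.cases(lp$profiles))
    d <- do.call(rbind, lapply(ok, function(bk)
      data.frame(unit = bk, stage = lp$stage[bk],
                 bin = seq_len(ncol(lp$profiles)), value = lp$profiles[bk, ])))
    a <- suppressWarnings(laminar_stage_anova(d, posthoc = FALSE))
    a$effects$p[a$effects$effect == "stage:bin"] < 0.01
  }, NA)
  expect_gte(sum(hits), 4)
})
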