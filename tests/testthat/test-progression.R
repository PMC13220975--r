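# Training-progression analysis: subcategory sorting, 99-block axis,
# peristimulus normalization and the repeated-measures stage ANOVA.

test_that("subcategory sorting retains eight combinations and drops the rest", {
  states <- c("persistent", "persistent", "disengaged", "disengaged",
              "attentive", "attentive", "persistent", "disengaged")
  outcomes <- c("hit", "miss", "hit", "correct_rejection",
                "correct_rejection", "false_alarm", "false_alarm", "miss")
  sc <- sort_subcategories(states, outcomes)
  expect_length(sc$index, 8)
  expect_equal(sc$index[["persistent.hit"]], 1L)
  expect_equal(sc$index[["attentive.correct_rejection"]], 5L)
  # excluded: persistent miss and disengaged hit
  expect_equal(sum(sc$dropped), 2L)
  expect_setequal(names(sc$dropped), c("persistent.miss", "disengaged.hit"))
  # chronological order preserved
  sc2 <- sort_subcategories(rep("attentive", 5), rep("hit", 5))
  expect_equal(sc2$index[["attentive.hit"]], 1:5)
})

test_that("progression blocks split as equally as possible, remainder first", {
  b1 <- progression_blocks(1:99, 99)
  expect_true(all(lengths(b1$blocks) == 1))
  b2 <- progression_blocks(1:198, 99)
  expect_true(all(lengths(b2$blocks) == 2))
  # 200 = 99 x 2 + 2: the two extra trials go to the earliest blocks
  b3 <- progression_blocks(1:200, 99)
  expect_equal(lengths(b3$blocks), c(3, 3, rep(2, 97)))
  # stages split 33/33/33
  expect_equal(as.vector(table(b3$stage)), c(33, 33, 33))
  # conservation for arbitrary sizes
  set.seed(5)
  for (n in sample(1:400, 15)) {
    bb <- progression_blocks(seq_len(n), 99)
    expect_equal(sum(lengths(bb$blocks)), n)
    expect_equal(unlist(bb$blocks), seq_len(n))
    expect_equal(bb$flagged_empty, n < 99)
  }
  expect_error(progression_blocks(integer(0)), "empty")
})

test_that("peristimulus normalization behaves per trial", {
  b <- fx_bundle()
  bm <- b$mice$m1
  tt <- bm$trials
  idx <- which(tt$latent_state == "persistent" & tt$outcome == "hit")[1:12]
  bl <- progression_blocks(idx, 6)
  # wheel speed: each trial curve is mean-subtracted by its prestimulus mean
  pw <- peristim_average(bm, idx, bl, "wheel_speed", n_bins = 40)
  pre <- pw$time < 0
  # a single-trial block preserves the per-trial normalization exactly
  expect_lt(max(abs(rowMeans(pw$block_curves[, pre]))), 1e-9)
  # z-scored eye traces: prestimulus mean 0, SD 1 per trial
  pe <- peristim_average(bm, idx, bl, "pupil_diameter", n_bins = 40)
  expect_lt(max(abs(rowMeans(pe$block_curves[, pre]))), 1e-9)
  one <- peristim_average(bm, idx[1], progression_blocks(idx[1], 1),
                          "pupil_diameter", n_bins = 40)
  expect_equal(sd(one$block_curves[1, pre]), 1, tolerance = 1e-6)
  # z-scoring an already z-scored trace is the identity (up to the floor)
  y <- as.numeric(one$block_curves[1, ])
  z2 <- (y - mean(y[pre])) / sd(y[pre])
  expect_equal(z2, y, tolerance = 1e-6)
  expect_equal(pw$normalization, "mean_subtracted")
  expect_equal(pe$normalization, "z_scored")
  expect_error(peristim_average(bm, idx, bl, "body_temperature"), "unknown")
})

test_that("the mixed stage ANOVA matches a sums-of-squares oracle", {
  set.seed(23)
  d <- expand.grid(unit = 1:9, bin = 1:4)
  d$stage <- factor(c("early", "mid", "late")[ceiling(d$unit / 3)],
                    levels = c("early", "mid", "late"))
  d$value <- rnorm(nrow(d)) + as.numeric(d$stage) * 0.5 + d$bin * 0.2
  a <- stage_anova(d)
  o <- oracle_mixed_anova(d)
  eff <- function(nm) a$effects[a$effects$effect == nm, ]
  expect_equal(eff("stage")$F, o$F_stage, tolerance = 1e-8)
  expect_equal(eff("bin")$F, o$F_bin, tolerance = 1e-8)
  expect_equal(eff("stage:bin")$F, o$F_int, tolerance = 1e-8)
  expect_equal(eff("stage")$df1, 2); expect_equal(eff("stage")$df2, 6)
  expect_equal(eff("bin")$df2, 18)
  # identical data in all groups: the same unit profiles appear in every
  # stage, so the stage effect vanishes exactly
  d0 <- d
  d0$value <- as.numeric(d0$bin) + rep(rep(c(0.1, 0.4, 0.9), 3), 4)
  a0 <- suppressWarnings(stage_anova(d0))
  expect_lt(a0$effects$F[a0$effects$effect == "stage"], 1e-10)
  expect_false(any(a0$posthoc$significant))
  # units with missing cells are dropped with a warning
  expect_warning(stage_anova(d[-1, ]), "missing cells")
  expect_error(stage_anova(d[d$stage == "early", ]), "2 stages")
})

test_that("growing prestimulus wheel acceleration yields a stage-time interaction", {
  hits <- vapply(1:6, function(s) {
    cf <- mouse_config("m1", n_sessions = 6, trials_per_session = 100,
                       seed = s + 200, n_channels = 3,
                       landmark_depth_mm = 0.02, dipole_depth_mm = 0.02,
                       wheel_accel_gain = 6)
    b <- gen_dataset(list(cf), signals = c("licks", "encoder", "keypoints"))
    bm <- b$mice$m1
    tt <- bm$trials
    sc <- sort_subcategories(tt$latent_state, tt$outcome)
    idx <- sc$index[["persistent.hit"]]
    bl <- progression_blocks(idx, 12)
    pp <- peristim_average(bm, idx, bl, "wheel_speed", n_bins = 20)
    ok <- which(stats::complete.cases(pp$block_curves))
    d <- do.call(rbind, lapply(ok, function(bk)
      data.frame(unit = bk, stage = pp$stage[bk], bin = 1:20,
                 value = pp$block_curves[bk, ])))
    a <- suppressWarnings(stage_anova(d, posthoc = FALSE))
    a$effects$p[a$effects$effect == "stage:bin"] < 0.01
  }, NA)
  expect_gte(sum(hits), 5)
})
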