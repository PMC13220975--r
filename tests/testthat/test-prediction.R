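# State prediction: block shuffling, bagged trees with swapped halves,
# ROC/AUC oracles, asymptotic fits, controls and regressions.

test_that("block shuffling permutes blocks and preserves within-block order", {
  x <- data.frame(v = 1:10)
  expect_equal(block_shuffle(x, block = 25, seed = 1)$v, 1:10)  # one block
  # block = 1 is a full row permutation
  p1 <- block_shuffle_index(100, block = 1, seed = 2)
  expect_setequal(p1, 1:100)
  expect_false(identical(p1, 1:100))
  # 100 rows in blocks of 25: multiset preserved, within-block adjacency kept
  p <- block_shuffle_index(100, block = 25, seed = 3)
  expect_setequal(p, 1:100)
  pos <- order(p)  # position of each row in the output
  internal <- setdiff(1:99, c(25, 50, 75))  # pairs not straddling blocks
  expect_true(all(pos[internal + 1] == pos[internal] + 1))
})

test_that("bagged prediction scores every trial once and is deterministic", {
  pf <- fx_pred()
  n <- 600
  rows <- round(seq(1, nrow(pf$x), length.out = n))  # span all sessions
  x <- pf$x[rows, ]; y <- pf$y[rows]
  run <- train_predict(x, y, seed = 5)
  expect_false(anyNA(run$scores))
  expect_equal(rowSums(run$scores), rep(1, n))
  expect_equal(sort(unique(run$split)), c(1L, 2L))
  run2 <- train_predict(x, y, seed = 5)
  expect_identical(run$scores, run2$scores)
  expect_error(train_predict(x, y, pool = character(0)), "empty")
  # a perfectly informative feature yields near-perfect AUC for all states
  x$oracle_code <- as.numeric(y) + rnorm(n, 0, 0.01)
  run3 <- train_predict(x, y, pool = "oracle_code", seed = 6)
  pr <- pooled_roc(list(run3), y)
  expect_true(all(vapply(pr, `[[`, 0, "auc") > 0.97))
})

test_that("a state confined to one block triggers the stratified fallback", {
  set.seed(8)
  n <- 200
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- factor(rep("persistent", n), levels = c("persistent", "disengaged", "attentive"))
  y[1:5] <- "disengaged"  # rarer than any half can guarantee by chance
  expect_warning(run <- train_predict(x, y, seed = 1, block = 100), "stratified")
  expect_false(anyNA(run$scores))
})

test_that("ROC/AUC matches the pairwise Mann-Whitney oracle and pROC", {
  # hand-listed pairs with a tie
  sc <- c(0.9, 0.4, 0.4, 0.2)
  lb <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(sc, lb)
  expect_equal(r$auc, oracle_auc(sc, lb))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  set.seed(11)
  for (i in 1:10) {
    sc <- round(runif(40), 2)  # rounding forces ties
    lb <- runif(40) < 0.4
    if (!any(lb) || all(lb)) next
    expect_equal(roc_curve(sc, lb)$auc, oracle_auc(sc, lb))
    expect_equal(roc_curve(sc, lb)$auc,
                 as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                                direction = "<"))))
  }
  # monotone transforms leave the AUC unchanged
  sc <- runif(100); lb <- runif(100) < 0.5
  expect_equal(roc_curve(sc, lb)$auc, roc_curve(exp(3 * sc), lb)$auc)
  # degenerate class
  expect_true(roc_curve(sc, rep(FALSE, 100))$flagged)
  # label-independent scores sit at chance
  set.seed(12)
  r0 <- roc_curve(runif(20000), runif(20000) < 0.3)
  expect_lt(abs(r0$auc - 0.5), 0.02)
})

test_that("the asymptotic exponential fit recovers its parameters", {
  y <- 0.9 - 0.4 * exp(-0.8 * (1:8))
  ft <- fit_asymptotic(1:8, y)
  expect_lt(abs(ft$a - 0.9), 1e-6)
  expect_lt(abs(ft$b - 0.4), 1e-6)
  expect_lt(abs(ft$k - 0.8), 1e-6)
  expect_equal(ft$r_squared, 1, tolerance = 1e-9)
  # constant curve: rate unidentifiable, flagged
  expect_true(fit_asymptotic(1:8, rep(0.7, 8))$flagged)
  # noisy recovery: k within 20% on average at sigma = 0.01
  set.seed(31)
  ks <- replicate(25, fit_asymptotic(1:8, y + rnorm(8, 0, 0.01))$k)
  expect_lt(abs(mean(ks) - 0.8) / 0.8, 0.2)
})

test_that("single-variable ranking finds a planted coupling", {
  pf <- fx_pred()
  n <- 800
  set.seed(13)
  x <- data.frame(matrix(rnorm(n * 8), n, 8))
  colnames(x) <- nonperformance_vars()
  y <- pf$y[round(seq(1, nrow(pf$x), length.out = n))]
  # only prestimulus licking carries state information
  x$prestim_lick_rate <- as.numeric(y) + rnorm(n, 0, 0.3)
  rk <- single_variable_rank(x, y, n_iter = 3, seed = 2)
  expect_equal(rk$ranking[1], "prestim_lick_rate")
  expect_false(rk$flagged)
  # with no couplings, everything sits at chance and the ranking is flagged
  n2 <- 1200
  set.seed(14)
  x0 <- data.frame(matrix(rnorm(n2 * 8), n2, 8))
  colnames(x0) <- nonperformance_vars()
  y0 <- pf$y[round(seq(1, nrow(pf$x), length.out = n2))]
  rk0 <- single_variable_rank(x0, y0, n_iter = 6, seed = 2)
  expect_true(rk0$flagged)
  expect_true(all(abs(rk0$auc$auc - 0.5) < 0.12))
})

test_that("row shuffling leaves accuracy intact while full shuffling removes it", {
  pf <- fx_pred()
  rows <- round(seq(1, nrow(pf$x), length.out = 1500))
  x <- pf$x[rows, ]; y <- pf$y[rows]
  base <- train_predict(x, y, seed = 3)
  auc_base <- mean(vapply(pooled_roc(list(base), y), `[[`, 0, "auc"))
  rowsh <- control_predictions(list(m1 = x), list(m1 = y), "row_shuffle",
                               n_iter = 4, seed = 4)
  expect_lt(abs(mean(rowsh$auc) - auc_base), 0.05)
  full <- control_predictions(list(m1 = x), list(m1 = y), "full_shuffle",
                              n_iter = 4, seed = 4)
  expect_true(all(abs(full$auc - 0.5) < 0.06))
  expect_error(control_predictions(list(m1 = x), list(m1 = y), "nonsense"))
})

test_that("predictor subsets restrict the candidate pools", {
  pf <- fx_pred()
  rows <- round(seq(1, nrow(pf$x), length.out = 800))
  x <- pf$x[rows, ]; y <- pf$y[rows]
  phys <- control_predictions(list(m1 = x), list(m1 = y), "subset_physio",
                              n_iter = 2, seed = 6, pool_sizes = c(1, 4))
  expect_equal(sort(unique(phys$pool_size)), c(1, 4))
  expect_true(all(phys$auc > 0.4))
  inc <- control_predictions(list(m1 = x), list(m1 = y), "always_include_var",
                             n_iter = 2, seed = 6, var = "prestim_lick_rate",
                             pool_sizes = c(2, 4))
  expect_equal(nrow(inc), 2 * 3)
})

test_that("regression controls separate planted signal from shuffled response", {
  set.seed(17)
  n <- 600
  x <- data.frame(matrix(rnorm(n * 8), n, 8))
  colnames(x) <- nonperformance_vars()
  resp <- 0.8 * x$pupil_diameter + rnorm(n, 0, 0.5)
  rc <- regression_controls(x, resp, seed = 1)
  expect_equal(rc$branch, "glm")
  med <- with(subset(rc$t_table, condition == "real"),
              tapply(abs(t), predictor, median))
  expect_equal(names(which.max(med)), "pupil_diameter")
  med_sh <- with(subset(rc$t_table, condition == "shuffled"),
                 tapply(t, predictor, median))
  expect_lt(max(abs(med_sh)), 2.5)
  expect_lt(rc$friedman$p_value, 0.01)
  # multinomial branch parses t statistics by state
  y <- factor(ifelse(x$wheel_speed > 0.5, "attentive",
                     ifelse(x$wheel_speed < -0.5, "disengaged", "persistent")),
              levels = c("persistent", "disengaged", "attentive"))
  rcm <- regression_controls(x, y, seed = 2)
  expect_equal(rcm$branch, "mnr")
  expect_setequal(unique(rcm$friedman$state),
                  c("persistent", "disengaged", "attentive"))
  medm <- with(subset(rcm$t_table, condition == "real"),
               tapply(abs(t), predictor, median))
  expect_equal(names(which.max(medm)), "wheel_speed")
})
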