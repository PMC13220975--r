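# State prediction from nonperformance variables: block shuffling, bagged
# decision trees with swapped-halves evaluation, pooled ROC/AUC, the
# asymptotic-exponential fit of AUC versus predictor-pool size, and the
# control analyses (cross-mouse, shuffles, GLM/MNR).

#' Shuffle table rows in consecutive blocks
#'
#' Rows are partitioned into consecutive blocks of `block` trials (the last
#' block may be short); the block order is permuted while the within-block
#' order is preserved. Columns are untouched. This deconstructs the
#' moving-average autocorrelation without destroying local structure.
#'
#' @param n number of rows.
#' @param block block size (default 25).
#' @param seed integer seed.
#' @return integer permutation of `1:n`.
#' @export
block_shuffle_index <- function(n, block = 25, seed = NULL) {
  if (block < 1) stopf("block must be >= 1")
  starts <- seq(1L, n, by = block)
  blocks <- lapply(starts, function(s) s:min(s + block - 1L, n))
  with_seed(seed, unlist(blocks[sample(length(blocks))]))
}

#' @rdname block_shuffle_index
#' @param x data.frame or matrix whose rows are shuffled.
#' @return for `block_shuffle`: `x` with permuted rows.
#' @export
block_shuffle <- function(x, block = 25, seed = NULL) {
  x[block_shuffle_index(nrow(x), block, seed), , drop = FALSE]
}

# fit a 30-tree bagged ensemble (fully grown trees) and return per-class
# vote fractions for newdata, with zero columns for classes absent from
# training
bagged_scores <- function(x_train, y_train, x_new, ntree, seed) {
  y_train <- droplevels(factor(y_train, levels = STATE_LEVELS))
  fit <- with_seed(seed,
    randomForest::randomForest(x = x_train, y = y_train, ntree = ntree,
                               mtry = ncol(x_train), nodesize = 1,
                               replace = TRUE))
  pr <- stats::predict(fit, newdata = x_new, type = "prob")
  out <- matrix(0, nrow(x_new), length(STATE_LEVELS),
                dimnames = list(NULL, STATE_LEVELS))
  out[, colnames(pr)] <- pr
  out
}

#' Bagged-tree state prediction with swapped halves
#'
#' Block-shuffles the trials, splits them 1:1, trains a bagged ensemble of
#' 30 fully grown decision trees on each half and scores the other, then
#' recombines the two held-out halves into chronological order. The class
#' score is the fraction of tree votes.
#'
#' @param x data.frame of predictor columns (chronological rows, one mouse).
#' @param y factor of tripartite state labels (same length).
#' @param pool character vector of predictor names to use.
#' @param seed integer seed.
#' @param block shuffle block size (default 25).
#' @param ntree learning cycles (default 30).
#' @return list of class `prediction_run`: `scores` (n x 3 matrix, rows in
#'   chronological order, rows sum to 1), `predicted` (factor), `pool`,
#'   `split` (half assignment in chronological order).
#' @export
train_predict <- function(x, y, pool = colnames(x), seed = NULL,
                          block = 25, ntree = 30) {
  if (length(pool) == 0) stopf("train_predict: empty variable pool")
  if (!all(pool %in% colnames(x))) stopf("train_predict: unknown pool variables")
  n <- nrow(x)
  y <- factor(y, levels = STATE_LEVELS)
  present <- levels(droplevels(y))
  perm <- block_shuffle_index(n, block, fan_seed(seed, "perm"))
  nA <- floor(n / 2)
  ok <- function(p) all(present %in% y[p[1:nA]]) && all(present %in% y[p[(nA + 1):n]])
  tries <- 0L
  while (!ok(perm) && tries < 20L) {
    tries <- tries + 1L
    perm <- block_shuffle_index(n, block, fan_seed(seed, "perm", tries))
  }
  if (ok(perm)) {
    A <- perm[1:nA]; B <- perm[(nA + 1):n]
  } else {
    warnf("train_predict: a state is absent from a training half; using a stratified split")
    halves <- with_seed(fan_seed(seed, "strat"), {
      A <- integer(0); B <- integer(0)
      for (st in present) {
        idx <- sample(which(y == st))
        k <- ceiling(length(idx) / 2)
        A <- c(A, idx[seq_len(k)])
        if (length(idx) > k) B <- c(B, idx[(k + 1):length(idx)])
      }
      list(A = A, B = B)
    })
    A <- halves$A; B <- halves$B
  }
  xs <- x[, pool, drop = FALSE]
  scores <- matrix(NA_real_, n, length(STATE_LEVELS),
                   dimnames = list(NULL, STATE_LEVELS))
  scores[B, ] <- bagged_scores(xs[A, , drop = FALSE], y[A],
                               xs[B, , drop = FALSE], ntree, fan_seed(seed, "fitA"))
  scores[A, ] <- bagged_scores(xs[B, , drop = FALSE], y[B],
                               xs[A, , drop = FALSE], ntree, fan_seed(seed, "fitB"))
  split_half <- integer(n); split_half[A] <- 1L; split_half[B] <- 2L
  structure(list(
    scores = scores,
    predicted = factor(STATE_LEVELS[max.col(scores, ties.method = "first")],
                       levels = STATE_LEVELS),
    pool = pool, split = split_half
  ), class = "prediction_run")
}

#' ROC curve and trapezoidal AUC for one positive class
#'
#' Thresholds sweep the distinct score values; tied scores move as one
#' group, so the trapezoid through tied thresholds equals the mid-rank
#' Mann-Whitney statistic.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector marking the positive class.
#' @return list with `fpr`, `tpr` (nondecreasing from (0,0) to (1,1)) and
#'   `auc`; `auc` is `NA` with `flagged = TRUE` when a class is empty.
#' @export
roc_curve <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0)
    return(list(fpr = NA, tpr = NA, auc = NA_real_, flagged = TRUE))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- positive[o]
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tied group
  tp <- cumsum(p)[last] / n_pos
  fp <- cumsum(!p)[last] / n_neg
  fpr <- c(0, fp); tpr <- c(0, tp)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc, flagged = FALSE)
}

#' Pool ROC curves over a group of prediction iterations
#'
#' Concatenates (score, label) pairs across all supplied runs and computes
#' one one-vs-rest ROC per state.
#'
#' @param runs list of `prediction_run` objects (same mouse and pool size).
#' @param labels factor of true states (recycled across runs).
#' @return named list (per state) of [roc_curve()] results, each carrying
#'   `n_pooled_iterations`.
#' @export
pooled_roc <- function(runs, labels) {
  labels <- factor(labels, levels = STATE_LEVELS)
  all_scores <- do.call(rbind, lapply(runs, `[[`, "scores"))
  all_labels <- rep(as.character(labels), length(runs))
  out <- lapply(STATE_LEVELS, function(st) {
    r <- roc_curve(all_scores[, st], all_labels == st)
    r$n_pooled_iterations <- length(runs)
    r
  })
  names(out) <- STATE_LEVELS
  out
}

#' Fit the asymptotic exponential model to an AUC curve
#'
#' Nonlinear least squares of `y = a - b * exp(-k * x)` with multi-start
#' initialization over the rate parameter. The p-value for `k` comes from
#' the asymptotic normal approximation of the NLS estimate.
#'
#' @param x predictor-pool sizes.
#' @param y AUC values.
#' @return list with `a`, `b`, `k`, `r_squared`, `p_k`, `flagged` (TRUE on
#'   degeneracy or non-convergence, with `NA` parameters).
#' @export
fit_asymptotic <- function(x, y) {
  flagged <- list(a = NA_real_, b = NA_real_, k = NA_real_,
                  r_squared = NA_real_, p_k = NA_real_, flagged = TRUE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || stats::sd(y) < 1e-10) return(flagged)
  best <- NULL
  for (k0 in c(0.05, 0.2, 0.5, 1, 2, 5)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a - b * exp(-k * xx),
                        data = list(y = y, xx = x),
                        start = list(a = max(y), b = max(max(y) - min(y), 1e-3), k = k0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) return(flagged)
  cf <- summary(best$fit)$coefficients
  tss <- sum((y - mean(y))^2)
  list(a = cf["a", 1], b = cf["b", 1], k = cf["k", 1],
       r_squared = 1 - best$rss / tss,
       p_k = cf["k", 4], flagged = FALSE)
}

#' AUC as a function of predictor-pool size with asymptotic fits
#'
#' For each pool size, runs `n_iter` prediction iterations, each with a
#' pool of that many variables drawn at random without replacement, pools
#' the (score, label) pairs per group, and fits the asymptotic exponential
#' per state. Per-iteration AUC averaging is available as an alternative
#' aggregation.
#'
#' @param x predictor data.frame (one mouse, chronological).
#' @param y factor of state labels.
#' @param pool_sizes integer vector (default 1:8).
#' @param n_iter iterations per pool size (default 100).
#' @param seed integer seed.
#' @param variables candidate variables (default the eight nonperformance
#'   variables present in `x`).
#' @param aggregate `"pooled"` (default: one ROC over all iterations) or
#'   `"mean"` (average of per-iteration AUCs).
#' @param block,ntree passed to [train_predict()].
#' @return list with `auc` (data.frame state, pool_size, auc) and `fits`
#'   (per-state [fit_asymptotic()] results).
#' @export
auc_vs_pool_size <- function(x, y, pool_sizes = 1:8, n_iter = 100, seed = 1,
                             variables = intersect(nonperformance_vars(), colnames(x)),
                             aggregate = c("pooled", "mean"),
                             block = 25, ntree = 30) {
  aggregate <- match.arg(aggregate)
  if (max(pool_sizes) > length(variables))
    stopf("pool size %d exceeds the %d available variables", max(pool_sizes), length(variables))
  rows <- list()
  for (m in pool_sizes) {
    runs <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      pool <- with_seed(fan_seed(seed, "pool", m, it),
                        sample(variables, m))
      runs[[it]] <- train_predict(x, y, pool, seed = fan_seed(seed, "iter", m, it),
                                  block = block, ntree = ntree)
    }
    if (aggregate == "pooled") {
      pr <- pooled_roc(runs, y)
      aucs <- vapply(pr, `[[`, 0, "auc")
    } else {
      per <- vapply(runs, function(r)
        vapply(pooled_roc(list(r), y), `[[`, 0, "auc"), numeric(3))
      aucs <- rowMeans(per)
    }
    rows[[length(rows) + 1]] <- data.frame(state = STATE_LEVELS, pool_size = m,
                                           auc = unname(aucs))
  }
  tab <- do.call(rbind, rows)
  fits <- lapply(STATE_LEVELS, function(st) {
    d <- tab[tab$state == st, ]
    fit_asymptotic(d$pool_size, d$auc)
  })
  names(fits) <- STATE_LEVELS
  list(auc = tab, fits = fits)
}

#' Per-variable AUC with ranking by mean AUC across states
#'
#' Runs fixed single-variable prediction iterations for every variable and
#' ranks variables by their across-state mean pooled AUC. When no variable
#' beats chance by a meaningful margin the ranking is flagged arbitrary.
#'
#' @param x predictor data.frame.
#' @param y factor of state labels.
#' @param n_iter iterations per variable (default 20).
#' @param seed integer seed.
#' @param variables variables to rank.
#' @param block,ntree passed to [train_predict()].
#' @return list with `auc` (data.frame variable, state, auc), `ranking`
#'   (variables by decreasing mean AUC) and `flagged`.
#' @export
single_variable_rank <- function(x, y, n_iter = 20, seed = 1,
                                 variables = intersect(nonperformance_vars(), colnames(x)),
                                 block = 25, ntree = 30) {
  rows <- list()
  for (v in variables) {
    runs <- lapply(seq_len(n_iter), function(it)
      train_predict(x, y, v, seed = fan_seed(seed, "single", v, it),
                    block = block, ntree = ntree))
    aucs <- vapply(pooled_roc(runs, y), `[[`, 0, "auc")
    rows[[v]] <- data.frame(variable = v, state = STATE_LEVELS, auc = unname(aucs))
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  mean_auc <- tapply(tab$auc, tab$variable, mean)
  ranking <- names(sort(mean_auc, decreasing = TRUE))
  list(auc = tab, ranking = ranking,
       flagged = max(abs(mean_auc - 0.5)) < 0.05)
}

#' Control analyses for state prediction
#'
#' Re-runs the prediction under one of the control regimes: cross-mouse
#' transfer (all ordered predictor-predicted pairs, size-matched held-out
#' sets), row shuffling (trial order only), full shuffling (rows and each
#' predictor column independently), predictor subsets (physiologic/
#' behavioral or neurophysiologic), or forced inclusion/exclusion of one
#' variable in random pools.
#'
#' @param x_list named list (per mouse) of predictor data.frames.
#' @param y_list named list (per mouse) of state-label factors.
#' @param mode one of `"cross_mouse"`, `"row_shuffle"`, `"full_shuffle"`,
#'   `"subset_physio"`, `"subset_neuro"`, `"always_include_var"`,
#'   `"always_exclude_var"`.
#' @param n_iter iterations (default 20).
#' @param seed integer seed.
#' @param var variable for the forced-inclusion/exclusion modes.
#' @param pool_sizes pool sizes for the subset / forced modes.
#' @param block,ntree passed to [train_predict()].
#' @return data.frame of AUC values; columns depend on the mode.
#' @export
control_predictions <- function(x_list, y_list,
                                mode = c("cross_mouse", "row_shuffle", "full_shuffle",
                                         "subset_physio", "subset_neuro",
                                         "always_include_var", "always_exclude_var"),
                                n_iter = 20, seed = 1, var = "prestim_lick_rate",
                                pool_sizes = NULL, block = 25, ntree = 30) {
  mode <- match.arg(mode)
  mice <- names(x_list)
  if (mode == "cross_mouse") {
    if (length(mice) < 2) stopf("cross_mouse needs at least 2 mice")
    rows <- list()
    for (a in mice) for (b in mice) {
      if (a == b) {
        run <- train_predict(x_list[[a]], y_list[[a]],
                             seed = fan_seed(seed, "within", a),
                             block = block, ntree = ntree)
        aucs <- vapply(pooled_roc(list(run), y_list[[a]]), `[[`, 0, "auc")
      } else {
        na <- nrow(x_list[[a]]); nh <- floor(na / 2)
        perm_a <- block_shuffle_index(na, block, fan_seed(seed, "xa", a, b))
        perm_b <- block_shuffle_index(nrow(x_list[[b]]), block, fan_seed(seed, "xb", a, b))
        held <- perm_b[seq_len(min(nh, length(perm_b)))]  # size-matched held-out set
        sc1 <- bagged_scores(x_list[[a]][perm_a[1:nh], , drop = FALSE],
                             y_list[[a]][perm_a[1:nh]],
                             x_list[[b]][held, , drop = FALSE], ntree,
                             fan_seed(seed, "cm1", a, b))
        sc2 <- bagged_scores(x_list[[a]][perm_a[(nh + 1):na], , drop = FALSE],
                             y_list[[a]][perm_a[(nh + 1):na]],
                             x_list[[b]][held, , drop = FALSE], ntree,
                             fan_seed(seed, "cm2", a, b))
        lab <- as.character(y_list[[b]][held])
        aucs <- vapply(STATE_LEVELS, function(st)
          roc_curve(c(sc1[, st], sc2[, st]), rep(lab == st, 2))$auc, 0)
      }
      rows[[paste(a, b)]] <- data.frame(predictor = a, predicted = b,
                                        state = STATE_LEVELS, auc = unname(aucs))
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL
    return(out)
  }
  if (mode %in% c("row_shuffle", "full_shuffle")) {
    rows <- list()
    for (mo in mice) {
      x <- x_list[[mo]]; y <- y_list[[mo]]; n <- nrow(x)
      runs <- vector("list", n_iter)
      for (it in seq_len(n_iter)) {
        perm <- with_seed(fan_seed(seed, "rows", mo, it), sample(n))
        xs <- x[perm, , drop = FALSE]; ys <- y[perm]
        if (mode == "full_shuffle") {
          for (j in seq_len(ncol(xs))) {
            prm <- with_seed(fan_seed(seed, "col", mo, it, j), sample(n))
            xs[[j]] <- xs[[j]][prm]
          }
        }
        runs[[it]] <- train_predict(xs, ys, seed = fan_seed(seed, "ctrl", mo, it),
                                    block = block, ntree = ntree)
        attr(runs[[it]], "labels") <- ys
      }
      # labels follow the permuted rows, so pool manually
      aucs <- vapply(STATE_LEVELS, function(st) {
        sc <- unlist(lapply(runs, function(r) r$scores[, st]))
        lb <- unlist(lapply(runs, function(r) as.character(attr(r, "labels")) == st))
        roc_curve(sc, lb)$auc
      }, 0)
      rows[[mo]] <- data.frame(mouse = mo, state = STATE_LEVELS, auc = unname(aucs))
    }
    out <- do.call(rbind, rows); rownames(out) <- NULL
    return(out)
  }
  # subset and forced-variable modes reduce to auc_vs_pool_size over a
  # restricted candidate set
  subset_vars <- switch(mode,
    subset_physio = c("prestim_lick_rate", "wheel_speed", "pupil_diameter", "eyelid_aperture"),
    subset_neuro = c("prestim_pss", "evoked_lfp", "prestim_mua_power", "evoked_mua"),
    always_exclude_var = setdiff(nonperformance_vars(), var),
    always_include_var = nonperformance_vars())
  rows <- list()
  for (mo in mice) {
    vars <- intersect(subset_vars, colnames(x_list[[mo]]))
    sizes <- if (is.null(pool_sizes)) seq_along(vars) else pool_sizes
    if (mode == "always_include_var") {
      tabs <- list()
      for (m in sizes) {
        runs <- lapply(seq_len(n_iter), function(it) {
          others <- with_seed(fan_seed(seed, "inc", mo, m, it),
                              sample(setdiff(vars, var), m - 1))
          train_predict(x_list[[mo]], y_list[[mo]], c(var, others),
                        seed = fan_seed(seed, "inc2", mo, m, it),
                        block = block, ntree = ntree)
        })
        aucs <- vapply(pooled_roc(runs, y_list[[mo]]), `[[`, 0, "auc")
        tabs[[m]] <- data.frame(mouse = mo, state = STATE_LEVELS,
                                pool_size = m, auc = unname(aucs))
      }
      rows[[mo]] <- do.call(rbind, tabs)
    } else {
      res <- auc_vs_pool_size(x_list[[mo]], y_list[[mo]], pool_sizes = sizes,
                              n_iter = n_iter, seed = fan_seed(seed, "sub", mo),
                              variables = vars, block = block, ntree = ntree)
      rows[[mo]] <- cbind(mouse = mo, res$auc)
    }
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' GLM and multinomial-regression controls with leave-one-predictor-out
#'
#' GLM branch (numeric response, smoothed correctness): one predictor is
#' omitted per iteration and the t-statistics of the remaining seven are
#' accumulated (intercept always removed). MNR branch (factor response,
#' tripartite states): three-class multinomial regression with a rotated
#' reference category; t-statistics are parsed by state. Both branches are
#' repeated with a shuffled response, and real-versus-shuffled differences
#' are quantified with a Friedman test across predictors plus
#' Tukey-protected per-predictor post hocs (paired Wilcoxon, tested only
#' when the Friedman test is significant).
#'
#' @param x data.frame with the eight predictor columns (smoothed).
#' @param response numeric (GLM branch) or factor (MNR branch).
#' @param seed integer seed for the response shuffle.
#' @param alpha protection level for the post hocs (default 0.05).
#' @return list with `branch`, `t_table` (predictor, omitted, condition,
#'   t, and `state` for MNR), `friedman` (statistic, df, p per state or
#'   overall) and `posthoc`.
#' @export
regression_controls <- function(x, response, seed = 1, alpha = 0.05) {
  p <- ncol(x); vars <- colnames(x)
  is_glm <- is.numeric(response)
  shuffled <- with_seed(fan_seed(seed, "resp"), sample(response))
  glm_ts <- function(resp) {
    rows <- list()
    for (j in seq_len(p)) {
      d <- x[, -j, drop = FALSE]
      fit <- stats::lm(resp ~ 0 + ., data = cbind(resp = resp, d))
      tt <- summary(fit)$coefficients[, "t value"]
      rows[[j]] <- data.frame(predictor = names(d), omitted = vars[j],
                              t = unname(tt), stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }
  mnr_ts <- function(resp) {
    resp <- factor(resp, levels = intersect(STATE_LEVELS, unique(as.character(resp))))
    rows <- list()
    for (ref in levels(resp)) {
      rr <- stats::relevel(resp, ref = ref)
      for (j in seq_len(p)) {
        d <- x[, -j, drop = FALSE]
        fit <- nnet::multinom(rr ~ ., data = cbind(rr = rr, d), trace = FALSE)
        sm <- summary(fit)
        tt <- sm$coefficients / sm$standard.errors
        if (is.null(dim(tt))) tt <- matrix(tt, nrow = 1, dimnames = list(setdiff(levels(rr), ref), names(tt)))
        keep <- setdiff(colnames(tt), "(Intercept)")
        for (st in rownames(tt))
          rows[[length(rows) + 1]] <- data.frame(
            state = st, predictor = keep, omitted = vars[j], reference = ref,
            t = unname(tt[st, keep]), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  fr_test <- function(tab) {
    # Friedman over predictors; blocks are the leave-one-out slots
    wide <- lapply(vars, function(v) {
      d <- tab[tab$predictor == v, ]
      d$t[order(d$omitted, d$condition)]
    })
    len <- min(lengths(wide))
    m <- do.call(cbind, lapply(wide, function(v) v[seq_len(len)]))
    colnames(m) <- vars
    ft <- stats::friedman.test(m)
    data.frame(statistic = unname(ft$statistic), df = unname(ft$parameter),
               p_value = ft$p.value)
  }
  run <- if (is_glm) glm_ts else mnr_ts
  real <- cbind(run(response), condition = "real")
  shuf <- cbind(run(shuffled), condition = "shuffled")
  tab <- rbind(real, shuf)
  if (is_glm) {
    fr <- cbind(state = "overall", fr_test(tab))
  } else {
    fr <- do.call(rbind, lapply(unique(tab$state), function(st)
      cbind(state = st, fr_test(tab[tab$state == st, ]))))
  }
  posthoc <- NULL
  if (any(fr$p_value < alpha)) {
    posthoc <- do.call(rbind, lapply(vars, function(v) {
      tr <- sort(tab$t[tab$predictor == v & tab$condition == "real"])
      ts <- sort(tab$t[tab$predictor == v & tab$condition == "shuffled"])
      k <- min(length(tr), length(ts))
      pv <- tryCatch(stats::wilcox.test(tr[seq_len(k)], ts[seq_len(k)],
                                        paired = TRUE, exact = FALSE)$p.value,
                     error = function(e) NA_real_)
      data.frame(predictor = v, p_value = pv, stringsAsFactors = FALSE)
    }))
  }
  list(branch = if (is_glm) "glm" else "mnr", t_table = tab,
       friedman = fr, posthoc = posthoc)
}
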