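# Normalized training-progression analysis: state x outcome subcategories,
# 99-block axis, peristimulus averaging by stage, repeated-measures ANOVA.

# the 8 retained state x outcome combinations
RETAINED_SUBCATS <- c(
  "persistent.hit", "persistent.false_alarm",
  "attentive.hit", "attentive.false_alarm",
  "attentive.correct_rejection", "attentive.miss",
  "disengaged.correct_rejection", "disengaged.miss")

#' Sort trials into the eight retained state-outcome subcategories
#'
#' Unattended trials during persistent states (correct rejections, misses)
#' and attended trials during disengaged states (hits, false alarms) are
#' excluded; chronological order is preserved within each subcategory.
#'
#' @param states factor/character of tripartite states per trial.
#' @param outcomes factor/character of go/no-go outcomes per trial.
#' @return list of class `subcategory_index`: `index` (named list of
#'   chronological trial indices per retained subcategory) and `dropped`
#'   (named counts of excluded trials per dropped combination).
#' @export
sort_subcategories <- function(states, outcomes) {
  stopifnot(length(states) == length(outcomes))
  key <- paste(as.character(states), as.character(outcomes), sep = ".")
  idx <- lapply(RETAINED_SUBCATS, function(k) which(key == k))
  names(idx) <- RETAINED_SUBCATS
  dropped_keys <- setdiff(unique(key), RETAINED_SUBCATS)
  dropped <- vapply(dropped_keys, function(k) sum(key == k), 0L)
  structure(list(index = idx, dropped = dropped), class = "subcategory_index")
}

#' Split a subcategory into contiguous progression blocks
#'
#' Trials are split chronologically into `n_blocks` contiguous blocks as
#' equal as possible; remainder trials are assigned one each to the
#' earliest blocks. With fewer trials than blocks, trailing blocks are
#' empty and the result is flagged.
#'
#' @param trials chronological trial indices of one subcategory.
#' @param n_blocks number of blocks (default 99).
#' @return list of class `progression_blocks`: `blocks` (list of index
#'   vectors), `stage` (factor early/mid/late per block, thirds of the
#'   block axis), `flagged_empty`.
#' @export
progression_blocks <- function(trials, n_blocks = 99) {
  n <- length(trials)
  if (n == 0) stopf("progression_blocks: empty subcategory")
  base <- n %/% n_blocks
  extra <- n %% n_blocks
  sizes <- rep(base, n_blocks)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  blocks <- lapply(seq_len(n_blocks), function(b)
    if (sizes[b] == 0) integer(0) else trials[starts[b]:ends[b]])
  third <- n_blocks / 3
  stage <- factor(c("early", "mid", "late")[ceiling(seq_len(n_blocks) / third)],
                  levels = c("early", "mid", "late"))
  structure(list(blocks = blocks, stage = stage,
                 flagged_empty = any(sizes == 0)),
            class = "progression_blocks")
}

# resample one trial's peristimulus trace of `variable` onto the common
# bin grid (bin centers, s relative to stimulus onset)
peristim_trace <- function(streams, trials_session, i, variable, centers, binw) {
  ts <- trials_session$t_stim[i]
  switch(variable,
    lick_rate = {
      edges <- ts + c(centers - binw / 2, centers[length(centers)] + binw / 2)
      counts <- graphics::hist(streams$lick_times, breaks = edges, plot = FALSE,
                               right = FALSE)$counts
      counts / binw
    },
    wheel_speed = {
      sp <- wheel_speed(streams$encoder$voltage, streams$encoder$rate)
      t_enc <- (seq_along(sp) - 1) / streams$encoder$rate
      stats::approx(t_enc, sp, xout = ts + centers, rule = 2)$y
    },
    pupil_diameter = ,
    eyelid_aperture = {
      kp <- streams$keypoints
      arr <- if (variable == "pupil_diameter") kp$pupil else kp$eyelid
      ap <- vapply(seq_along(kp$time), function(k) frame_aperture(arr[k, , ]), 0)
      stats::approx(kp$time, ap, xout = ts + centers, rule = 2)$y
    },
    stopf("unknown peristimulus variable: %s", variable))
}

#' Peristimulus profiles averaged over progression blocks and stages
#'
#' Each trial's trace of the requested variable is resampled onto a common
#' peristimulus grid (`n_bins` bins across `window` seconds around
#' stimulus onset), normalized per trial (wheel speed mean-subtracted by
#' its own prestimulus mean; eye signals z-scored by prestimulus mean and
#' SD with a floor; lick rate raw), averaged within blocks, and summarized
#' per training stage as mean and standard error across blocks.
#'
#' @param bundle_mouse one mouse's entry of a `motistate_bundle`.
#' @param trial_idx chronological trial row numbers (into the mouse's
#'   trial table) of one subcategory.
#' @param blocks a [progression_blocks()] built from `trial_idx`.
#' @param variable one of `"lick_rate"`, `"wheel_speed"`,
#'   `"pupil_diameter"`, `"eyelid_aperture"`.
#' @param window peristimulus window (default `c(-1, 4)` s).
#' @param n_bins number of time bins (default 80).
#' @return list of class `peristim_profile`: `time` (bin centers),
#'   `block_curves` (blocks x bins matrix, empty blocks NA), `stage`
#'   (factor per block), `stage_mean`/`stage_se` (3 x bins),
#'   `normalization`.
#' @export
peristim_average <- function(bundle_mouse, trial_idx, blocks, variable,
                             window = c(-1, 4), n_bins = 80) {
  tt <- bundle_mouse$trials
  binw <- diff(window) / n_bins
  centers <- window[1] + (seq_len(n_bins) - 0.5) * binw
  norm <- switch(variable, wheel_speed = "mean_subtracted",
                 pupil_diameter = , eyelid_aperture = "z_scored", "raw")
  pre <- centers < 0
  trial_curve <- function(row) {
    d <- tt$day[row]
    sess <- bundle_mouse$streams[[d]]
    tr_s <- tt[tt$day == d, ]
    i <- tt$trial[row]
    y <- peristim_trace(sess, tr_s, i, variable, centers, binw)
    if (norm == "mean_subtracted") y <- y - mean(y[pre])
    if (norm == "z_scored") {
      s <- stats::sd(y[pre])
      floor_sd <- 1e-6 * max(diff(range(y)), 1e-12)
      y <- (y - mean(y[pre])) / max(s, floor_sd)
    }
    y
  }
  nb <- length(blocks$blocks)
  block_curves <- matrix(NA_real_, nb, n_bins)
  for (b in seq_len(nb)) {
    rows <- blocks$blocks[[b]]
    if (length(rows) == 0) next
    block_curves[b, ] <- colMeans(do.call(rbind, lapply(rows, trial_curve)))
  }
  stage_mean <- stage_se <- matrix(NA_real_, 3, n_bins,
                                   dimnames = list(c("early", "mid", "late"), NULL))
  for (st in c("early", "mid", "late")) {
    m <- block_curves[blocks$stage == st, , drop = FALSE]
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m)) {
      stage_mean[st, ] <- colMeans(m)
      stage_se[st, ] <- apply(m, 2, stats::sd) / sqrt(nrow(m))
    }
  }
  structure(list(time = centers, block_curves = block_curves,
                 stage = blocks$stage, stage_mean = stage_mean,
                 stage_se = stage_se, normalization = norm,
                 variable = variable),
            class = "peristim_profile")
}

#' Two-way mixed ANOVA of training stage with repeated measures
#'
#' Training stage is a between-unit factor (units are trial blocks pooled
#' across mice); the repeated-measure axis (peristimulus time bins or
#' laminar depth channels) is within-unit. The stage effect is tested
#' against the between-unit stratum; the repeated-measure and interaction
#' effects against the within-unit stratum. Tukey-protected pairwise
#' stage comparisons (early-vs-mid, early-vs-late) are evaluated at each
#' repeated-measure level, protected by the omnibus stage or interaction
#' test.
#'
#' @param data data.frame with columns `unit` (block identifier, unique
#'   across stages), `stage` (factor), `bin` (repeated measure) and
#'   `value`. Units with missing cells are dropped with a warning.
#' @param alpha protection level (default 0.05).
#' @param posthoc logical; compute the per-bin Tukey comparisons (default
#'   TRUE; disable for large simulation batches needing only the omnibus).
#' @return list of class `anova_result`: `effects` (data.frame effect,
#'   df1, df2, F, p), `posthoc` (data.frame bin, comparison, p_adj,
#'   significant).
#' @export
stage_anova <- function(data, alpha = 0.05, posthoc = TRUE) {
  data$unit <- factor(data$unit)
  data$stage <- factor(data$stage)
  data$bin <- factor(data$bin)
  if (nlevels(data$stage) < 2 || nlevels(data$bin) < 2)
    stopf("stage_anova: need >= 2 stages and >= 2 repeated-measure bins")
  n_bins <- nlevels(data$bin)
  cnt <- table(data$unit)
  bad <- names(cnt)[cnt < n_bins]
  if (length(bad)) {
    warnf("stage_anova: dropping %d unit(s) with missing cells", length(bad))
    data <- data[!data$unit %in% bad, ]
    data$unit <- droplevels(data$unit)
  }
  fit <- stats::aov(value ~ stage * bin + Error(unit/bin), data = data)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    row <- trimws(rownames(tab)) == term
    if (!any(row)) return(NULL)
    resid <- trimws(rownames(tab)) == "Residuals"
    data.frame(effect = term, df1 = tab[row, "Df"], df2 = tab[resid, "Df"],
               F = tab[row, "F value"], p = tab[row, "Pr(>F)"])
  }
  effects <- rbind(pick("Error: unit", "stage"),
                   pick("Error: unit:bin", "bin"),
                   pick("Error: unit:bin", "stage:bin"))
  rownames(effects) <- NULL
  protected <- any(effects$p[effects$effect %in% c("stage", "stage:bin")] < alpha,
                   na.rm = TRUE)
  ph <- NULL
  cmp_keep <- c("mid-early", "early-mid", "late-early", "early-late")
  rows <- list()
  if (posthoc) for (b in levels(data$bin)) {
    d <- data[data$bin == b, ]
    tk <- tryCatch(stats::TukeyHSD(stats::aov(value ~ stage, data = d))$stage,
                   error = function(e) NULL)
    if (is.null(tk)) next
    keep <- rownames(tk) %in% cmp_keep
    if (!any(keep)) next
    rows[[b]] <- data.frame(bin = b, comparison = rownames(tk)[keep],
                            p_adj = tk[keep, "p adj"],
                            significant = protected & tk[keep, "p adj"] < alpha,
                            stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    ph <- do.call(rbind, rows); rownames(ph) <- NULL
  }
  structure(list(effects = effects, posthoc = ph, protected = protected),
            class = "anova_result")
}
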