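# Tripartite state labeling from smoothed licking and correctness,
# thresholded per mouse.

#' Binarize smoothed lick rates by the two lowest histogram bins
#'
#' The mouse's concatenated smoothed lick rates are partitioned into a
#' 100-bin equal-width histogram over the observed range; trials at or
#' below the upper edge of the second bin are low/no licking, all others
#' moderate/high.
#'
#' @param rates concatenated smoothed lick rates for one mouse.
#' @param n_bins histogram bin count (default 100).
#' @return list with `axis` (factor `low_no` / `moderate_high`) and
#'   `cutoff` (the bin-2 upper edge).
#' @export
binarize_licking <- function(rates, n_bins = 100) {
  if (length(rates) == 0) stopf("binarize_licking: no data")
  rng <- range(rates)
  if (diff(rng) == 0) {
    if (rng[1] == 0)
      return(list(axis = factor(rep("low_no", length(rates)),
                                levels = c("low_no", "moderate_high")),
                  cutoff = 0))
    stopf("binarize_licking: degenerate histogram (all rates identical at %g)", rng[1])
  }
  cutoff <- rng[1] + 2 * diff(rng) / n_bins
  axis <- factor(ifelse(rates <= cutoff, "low_no", "moderate_high"),
                 levels = c("low_no", "moderate_high"))
  list(axis = axis, cutoff = cutoff)
}

#' Binarize smoothed correctness by the per-mouse 75th quantile
#'
#' Trials at or above the 75th quantile (linear-interpolation sample
#' quantile) of the mouse's concatenated smoothed correctness are good
#' performance; the cutoff is never pooled across mice.
#'
#' @param correctness concatenated smoothed correctness for one mouse.
#' @param q quantile (default 0.75).
#' @return list with `axis` (factor `chance` / `good`) and `cutoff`.
#' @export
binarize_correctness <- function(correctness, q = 0.75) {
  if (length(correctness) == 0) stopf("binarize_correctness: no data")
  cutoff <- unname(stats::quantile(correctness, q, type = 7))
  axis <- factor(ifelse(correctness >= cutoff, "good", "chance"),
                 levels = c("chance", "good"))
  list(axis = axis, cutoff = cutoff)
}

#' Merge the two binary axes into the tripartite state
#'
#' Good performance is attentive; remaining low/no-licking trials are
#' disengaged; the rest (moderate/high licking at chance) are persistent.
#' The (low/no licking, good performance) combination never occurred in
#' the original recordings; when it does occur, attentive takes
#' precedence and the conflict is counted (a warning fires above 1%).
#'
#' @param lick_axis factor from [binarize_licking()].
#' @param correctness_axis factor from [binarize_correctness()].
#' @return list with `state` (factor persistent/disengaged/attentive) and
#'   `n_conflicts`.
#' @export
tripartite <- function(lick_axis, correctness_axis) {
  stopifnot(length(lick_axis) == length(correctness_axis))
  good <- correctness_axis == "good"
  low <- lick_axis == "low_no"
  state <- ifelse(good, "attentive", ifelse(low, "disengaged", "persistent"))
  n_conflicts <- sum(good & low)
  if (n_conflicts > 0.01 * length(state))
    warnf("tripartite: %d trials (%.1f%%) combine low/no licking with good performance",
          n_conflicts, 100 * n_conflicts / length(state))
  list(state = factor(state, levels = STATE_LEVELS), n_conflicts = n_conflicts)
}

#' Label every trial with its motivation state
#'
#' Smooths whole-trial lick rate and correctness with the session-wise
#' moving mean, concatenates across days per mouse, applies the histogram
#' and quantile binarizations, and merges them into the tripartite state.
#'
#' @param features a [trial_features()] table (unsmoothed).
#' @param window smoothing window in trials (default 50).
#' @param n_bins lick histogram bins (default 100).
#' @param q correctness quantile (default 0.75).
#' @return data.frame of class `state_labels`: `mouse`, `day`, `trial`,
#'   `lick_axis`, `correctness_axis`, `state`, with per-mouse thresholds
#'   in `attr(, "thresholds")` and the conflict count in
#'   `attr(, "n_conflicts")`.
#' @export
label_states <- function(features, window = 50, n_bins = 100, q = 0.75) {
  out <- lapply(split(features, features$mouse), function(fm) {
    fm <- fm[order(fm$day, fm$trial), ]
    key <- fm$day
    lick_sm <- stats::ave(fm$whole_trial_lick_rate, key,
                          FUN = function(x) moving_mean(x, window))
    corr_sm <- stats::ave(fm$correctness, key,
                          FUN = function(x) moving_mean(x, window))
    bl <- binarize_licking(lick_sm, n_bins)
    bc <- binarize_correctness(corr_sm, q)
    tp <- tripartite(bl$axis, bc$axis)
    list(df = data.frame(mouse = fm$mouse, day = fm$day, trial = fm$trial,
                         lick_axis = bl$axis, correctness_axis = bc$axis,
                         state = tp$state, stringsAsFactors = FALSE),
         thr = data.frame(mouse = fm$mouse[1], lick_cutoff = bl$cutoff,
                          correctness_cutoff = bc$cutoff,
                          stringsAsFactors = FALSE),
         nc = tp$n_conflicts)
  })
  labels <- do.call(rbind, lapply(out, `[[`, "df"))
  rownames(labels) <- NULL
  attr(labels, "thresholds") <- do.call(rbind, lapply(out, `[[`, "thr"))
  attr(labels, "n_conflicts") <- sum(vapply(out, `[[`, 0, "nc"))
  class(labels) <- c("state_labels", "data.frame")
  labels
}
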