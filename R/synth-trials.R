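# Trial-level synthesis: constrained go/no-go sequences, latent motivation
# state timelines, outcomes and epoch timing.

#' Generate a pseudorandom go/no-go trial sequence
#'
#' Fair coin flips with rejection of any draw that would create a run of
#' identical trial types longer than `max_run`, emulating the training
#' constraint of no more than three consecutive repetitions. Counts are
#' approximately balanced but not forced to equality.
#'
#' @param n number of trials.
#' @param max_run maximum allowed run of identical types (default 3).
#' @param seed integer seed.
#' @return character vector of `"go"` / `"nogo"` of length `n`.
#' @export
gen_trial_sequence <- function(n, max_run = 3, seed = 1) {
  if (n < 1) stopf("n must be >= 1")
  if (max_run < 1) stopf("max_run must be >= 1")
  with_seed(seed, {
    types <- character(n)
    run <- 0L
    last <- ""
    for (i in seq_len(n)) {
      draw <- if (run >= max_run) {
        # the disallowed repetition is rejected at draw time: forced switch
        setdiff(c("go", "nogo"), last)
      } else {
        sample(c("go", "nogo"), 1)
      }
      draw <- draw[1]
      if (identical(draw, last)) run <- run + 1L else {last <- draw; run <- 1L}
      types[i] <- draw
    }
    types
  })
}

# Attentive discrimination accuracy on day d (1-based): chance on day 1,
# saturating toward ~0.98 at a rate set by learning_rate.
attentive_accuracy <- function(day, learning_rate) {
  0.5 + 0.48 * (1 - exp(-2 * learning_rate * (day - 1)))
}

# Probability that the mouse licks in the answer period given state,
# trial type and day.
response_prob <- function(state, trial_type, day, learning_rate) {
  acc <- attentive_accuracy(day, learning_rate)
  ifelse(state == "persistent", 0.95,
  ifelse(state == "disengaged", 0.03,
         ifelse(trial_type == "go", acc, 1 - acc)))
}

#' Generate the latent motivation-state timeline for one mouse
#'
#' A semi-Markov chain over persistent/disengaged/attentive with geometric
#' dwell times (mean `state_dwell_mean` trials). Transition weights depend
#' on the phase within the session (disengagement becomes likelier late in
#' a session) and on the training day (attentiveness becomes likelier with
#' learning). The state is redrawn at the start of each session from the
#' session-start weights, emulating re-engagement on a new day.
#'
#' @param config a [mouse_config()].
#' @return data.frame with columns `day`, `trial`, `state` plus per-trial
#'   tendencies for the eight nonperformance variables (columns named
#'   `tend_<variable>`).
#' @export
gen_state_timeline <- function(config) {
  stopifnot(inherits(config, "mouse_config"))
  ns <- config$n_sessions; nt <- config$trials_per_session
  # per-state dwell multipliers: disengaged (satiated) stretches persist
  # longer, attentive focus episodes are shorter but entered more often;
  # entry weights below compensate, so both state prevalences and the
  # run-length mean stay at their configured values (the mean run length
  # is the harmonic mixture of per-state dwells weighted by entry shares)
  dwell_mult <- c(persistent = 1, disengaged = 2.5, attentive = 2 / 3)
  with_seed(fan_seed(config$seed, "timeline"), {
    day <- rep(seq_len(ns), each = nt)
    trial <- rep(seq_len(nt), ns)
    frac <- (trial - 1) / max(1, nt - 1)
    state <- character(ns * nt)
    weights <- function(d, f) {
      # attentive weight grows with training so attentive stretches
      # concentrate where discrimination accuracy is high, keeping the
      # overall attentive share near the upper-quartile cut the labeling
      # uses; disengagement becomes likely only late in a session
      c(persistent = 0.75,
        disengaged = (0.05 + 1.6 * f^3) / 2.5,
        attentive  = 1.5 * (0.02 + 0.14 * config$learning_rate * (d - 1)) *
          (0.3 + 2.8 * f * (1 - f)))
    }
    draw_state <- function(d, f, exclude = NULL) {
      w <- weights(d, f)
      if (!is.null(exclude)) w <- w[setdiff(names(w), exclude)]
      sample(names(w), 1, prob = w)
    }
    draw_dwell <- function(st)
      1L + stats::rgeom(1, 1 / (config$state_dwell_mean * dwell_mult[[st]]))
    i <- 1L
    for (d in seq_len(ns)) {
      cur <- draw_state(d, 0)
      dwell <- draw_dwell(cur)
      for (t in seq_len(nt)) {
        if (dwell <= 0L) {
          cur <- draw_state(d, frac[i], exclude = cur)
          dwell <- draw_dwell(cur)
        }
        state[i] <- cur
        dwell <- dwell - 1L
        i <- i + 1L
      }
    }
    out <- data.frame(day = day, trial = trial, state = state,
                      stringsAsFactors = FALSE)
    for (v in nonperformance_vars()) {
      cp <- config$feature_coupling[[v]]
      mu <- cp$mean[state] + cp$drift * (day - 1)
      out[[paste0("tend_", v)]] <- mu + stats::rnorm(length(mu), 0, cp$sd)
    }
    # keep rates/powers physically nonnegative
    for (v in c("prestim_lick_rate", "pupil_diameter", "eyelid_aperture",
                "prestim_mua_power", "evoked_mua"))
      out[[paste0("tend_", v)]] <- pmax(out[[paste0("tend_", v)]], 0.01)
    out
  })
}

#' Build the trial table for one mouse
#'
#' Combines the constrained go/no-go sequence with the latent-state
#' timeline to draw outcomes and lay out epoch timing. Trials last 5 s
#' (1 s prestimulus, 0.2 s stimulus, 1.8 s answer, 2 s intertrial); a
#' false alarm extends the intertrial interval to 10 s (13 s trial).
#'
#' @param config a [mouse_config()].
#' @param timeline output of [gen_state_timeline()] (regenerated if NULL).
#' @return data.frame with one row per trial: `mouse`, `day`, `trial`,
#'   `trial_type`, `outcome`, `punished`, `latent_state`, `t_onset`,
#'   `t_stim` (stimulus onset), `duration` (s), plus the timeline tendency
#'   columns.
#' @export
gen_trial_table <- function(config, timeline = NULL) {
  stopifnot(inherits(config, "mouse_config"))
  if (is.null(timeline)) timeline <- gen_state_timeline(config)
  ns <- config$n_sessions; nt <- config$trials_per_session
  stopifnot(nrow(timeline) == ns * nt)
  pc <- pipeline_config()
  base_dur <- pc$prestim_dur + pc$stim_dur + pc$answer_dur + pc$iti_dur
  pun_dur <- pc$prestim_dur + pc$stim_dur + pc$answer_dur + pc$punished_iti_dur
  rows <- vector("list", ns)
  with_seed(fan_seed(config$seed, "trials"), {
    for (d in seq_len(ns)) {
      types <- gen_trial_sequence(nt, max_run = 3,
                                  seed = fan_seed(config$seed, "types", d))
      st <- timeline$state[timeline$day == d]
      p <- response_prob(st, types, d, config$learning_rate)
      licked <- stats::runif(nt) < p
      outcome <- ifelse(types == "go",
                        ifelse(licked, "hit", "miss"),
                        ifelse(licked, "false_alarm", "correct_rejection"))
      punished <- outcome == "false_alarm"
      duration <- ifelse(punished, pun_dur, base_dur)
      t_onset <- cumsum(c(0, duration[-nt]))
      rows[[d]] <- data.frame(
        mouse = config$mouse_id, day = d, trial = seq_len(nt),
        trial_type = types, outcome = outcome, punished = punished,
        latent_state = st, t_onset = t_onset,
        t_stim = t_onset + pc$prestim_dur, duration = duration,
        stringsAsFactors = FALSE)
    }
  })
  tt <- do.call(rbind, rows)
  cbind(tt, timeline[, grep("^tend_", names(timeline)), drop = FALSE])
}
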