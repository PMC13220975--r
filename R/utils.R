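# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not disturb the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a child seed deterministically from a parent seed and labels
#'
#' All randomness in the package fans out from one dataset-level seed; each
#' mouse/session/stream gets its own reproducible substream via this hash.
#'
#' @param seed parent integer seed.
#' @param ... labels (coerced to character) identifying the substream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
fan_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, keeps derived seeds valid R integers
  h <- as.numeric(seed) %% m
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0(":", paste(as.character(part), collapse = ",")))) {
      h <- (h * 131 + ch) %% m
    }
  }
  as.integer(h)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# state / outcome level sets used throughout
STATE_LEVELS <- c("persistent", "disengaged", "attentive")
OUTCOME_LEVELS <- c("hit", "miss", "correct_rejection", "false_alarm")

#' Names of the eight nonperformance variables
#'
#' The motor and physiologic per-trial metrics used for state prediction,
#' excluding whole-trial lick rate and correctness.
#' @return character vector of length 8.
#' @export
nonperformance_vars <- function() {
  c("prestim_lick_rate", "wheel_speed", "pupil_diameter", "eyelid_aperture",
    "prestim_pss", "evoked_lfp", "prestim_mua_power", "evoked_mua")
}
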