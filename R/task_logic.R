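#' Lever geometry
#'
#' Angular landmarks of the lever: a pull registers once the lever passes the
#' pull threshold (3 degrees), a hold only counts while the lever stays inside
#' the goal range (6--24 degrees), and the physical range ends at 30 degrees.
#'
#' @param pull_threshold Degrees; displacement registering a pull (default 3).
#' @param goal_low,goal_high Degrees; goal range for a successful hold
#'   (defaults 6 and 24).
#' @param range_max Degrees; end of the movement range (default 30).
#' @return An object of class `"lever_geometry"`.
#' @export
lever_geometry <- function(pull_threshold = 3, goal_low = 6, goal_high = 24,
                           range_max = 30) {
  if (!(0 < pull_threshold && pull_threshold < goal_low &&
          goal_low < goal_high && goal_high <= range_max)) {
    stop("invalid geometry: need 0 < pull_threshold < goal_low < goal_high <= range_max")
  }
  structure(list(pull_threshold = pull_threshold, goal_low = goal_low,
                 goal_high = goal_high, range_max = range_max),
            class = "lever_geometry")
}

#' Per-mouse scheduler state
#'
#' The adaptive controller's state for one mouse: training stage (1 =
#' habituation, any pull rewarded; 2 = adaptive hold-time), the current
#' required hold time (starts at 0, capped at 1 s), the consecutive count of
#' low-success days, and the last benchmark the requirement can be reset to
#' after two consecutive days below 10% success.
#'
#' @param mouse_id Mouse identifier.
#' @param stage 1 or 2.
#' @param required_hold_time Seconds, in `[0, 1]`.
#' @param consecutive_low_days Non-negative integer.
#' @param last_benchmark Seconds; requirement in force before the most recent
#'   upward update.
#' @return An object of class `"scheduler_state"`.
#' @export
scheduler_state <- function(mouse_id, stage = 1L, required_hold_time = 0,
                            consecutive_low_days = 0L, last_benchmark = 0) {
  stopifnot(stage %in% c(1L, 2L),
            required_hold_time >= 0, required_hold_time <= 1,
            consecutive_low_days >= 0)
  structure(list(mouse_id = mouse_id, stage = as.integer(stage),
                 required_hold_time = required_hold_time,
                 consecutive_low_days = as.integer(consecutive_low_days),
                 last_benchmark = last_benchmark),
            class = "scheduler_state")
}

#' Measure the hold time of a lever trajectory
#'
#' The hold time is the duration of the first maximal contiguous run of
#' samples inside the goal range, looking from the first sample at or above
#' the pull threshold onward. Leaving the goal range in either direction
#' (release below 6 degrees or overshoot above 24) ends the hold. Returns 0 if
#' the lever never enters the goal range. Durations are truncated at
#' `max_hold_s` (5 s), beyond which the task ends the trial.
#'
#' @param traj A [trajectory()] or a numeric vector of angles in degrees.
#' @param geom A [lever_geometry()].
#' @param fs Sampling rate, used when `traj` is a bare numeric vector.
#' @param max_hold_s Truncation ceiling in seconds (default 5).
#' @return Hold duration in seconds (`run length / fs`).
#' @examples
#' # 320 samples inside the goal range at 400 Hz -> 0.8 s
#' compute_hold_time(c(0, 4, rep(15, 320), 2))
#' @export
compute_hold_time <- function(traj, geom = lever_geometry(), fs = 400,
                              max_hold_s = 5) {
  angle <- if (inherits(traj, "trajectory")) {
    fs <- traj$fs
    traj$angle
  } else as.numeric(traj)
  i0 <- which(angle >= geom$pull_threshold)[1]
  if (is.na(i0)) return(0)
  seg <- angle[i0:length(angle)]
  inr <- seg >= geom$goal_low & seg <= geom$goal_high
  r <- rle(inr)
  k <- which(r$values)[1]
  if (is.na(k)) return(0)
  min(r$lengths[k] / fs, max_hold_s)
}

#' Classify a trial outcome
#'
#' Stage 1: any registered pull is rewarded. Stage 2: the trial succeeds iff
#' the achieved hold time is at least the required hold time (a tie counts as
#' success). The returned value carries a `"cues"` attribute with the audio
#' cue frequencies the task emits (2.5 kHz trial start; 5 kHz success, 1 kHz
#' failure).
#'
#' @param hold_time Achieved hold time in seconds.
#' @param state A [scheduler_state()].
#' @return Logical scalar with attribute `cues` (named numeric, Hz).
#' @export
classify_trial <- function(hold_time, state) {
  stopifnot(inherits(state, "scheduler_state"))
  success <- if (state$stage == 1L) TRUE else hold_time >= state$required_hold_time
  structure(success,
            cues = c(start = 2500, outcome = if (success) 5000 else 1000))
}

#' Summarise one mouse-day of trials
#'
#' @param mouse_id Mouse identifier.
#' @param day_index 1-based day in cage.
#' @param hold_times Numeric vector of the day's achieved hold times.
#' @param successes Logical vector of trial outcomes (same length).
#' @return An object of class `"day_summary"` with trial counts, success rate
#'   (`NA` on zero-trial days) and the type-7 75th percentile of all the
#'   day's hold times.
#' @export
day_summary <- function(mouse_id, day_index, hold_times = numeric(),
                        successes = logical()) {
  stopifnot(length(hold_times) == length(successes))
  n <- length(hold_times)
  structure(list(mouse_id = mouse_id, day_index = day_index,
                 n_trials = n, n_success = sum(successes),
                 success_rate = if (n > 0) mean(successes) else NA_real_,
                 hold_times = as.numeric(hold_times),
                 p75_hold = if (n > 0) {
                   unname(quantile(hold_times, 0.75, type = 7))
                 } else NA_real_),
            class = "day_summary")
}

#' Stage-1 to stage-2 advancement
#'
#' A mouse advances from the habituation stage to the adaptive stage,
#' effective the next day, once it performs at least `min_trials` pulls in a
#' single day. The required hold time starts at zero.
#'
#' @param day A [day_summary()] for the completed day.
#' @param state A [scheduler_state()] with `stage = 1`.
#' @param min_trials Pulls needed in one day to advance (default 100).
#' @return The updated [scheduler_state()].
#' @export
advance_stage <- function(day, state, min_trials = 100) {
  stopifnot(inherits(state, "scheduler_state"), state$stage == 1L)
  if (day$n_trials >= min_trials) {
    state$stage <- 2L
    state$required_hold_time <- 0
    state$last_benchmark <- 0
  }
  state
}

#' Nightly update of the required hold time
#'
#' At midnight the controller considers the completed day: the candidate new
#' requirement is the 75th percentile (type-7 linear interpolation) of all the
#' day's hold times, and it is adopted (capped at `cap_s` = 1 s) only if it
#' exceeds the current requirement, the day's success rate was at least
#' `min_sr` (30%) and the day had at least `min_trials` (100) attempts. When
#' an upward update is applied, the previous requirement is remembered as the
#' last benchmark. Independently, a day with success below `reset_sr` (10%)
#' -- including a zero-trial day -- increments a counter; at `reset_days` (2)
#' consecutive low days the requirement falls back to the last benchmark and
#' the counter clears.
#'
#' @param day A [day_summary()] of the completed day (stage-2 trials).
#' @param state A [scheduler_state()] with `stage = 2`.
#' @param cap_s Requirement ceiling (default 1 s).
#' @param min_trials,min_sr Gates for an upward update (defaults 100, 0.30).
#' @param reset_sr,reset_days Low-success reset rule (defaults 0.10, 2).
#' @return The updated [scheduler_state()].
#' @export
update_required_hold_time <- function(day, state, cap_s = 1,
                                      min_trials = 100, min_sr = 0.30,
                                      reset_sr = 0.10, reset_days = 2) {
  stopifnot(inherits(state, "scheduler_state"), state$stage == 2L)
  cand <- day$p75_hold
  sr <- day$success_rate
  if (day$n_trials >= min_trials && !is.na(sr) && sr >= min_sr &&
        !is.na(cand) && cand > state$required_hold_time) {
    new <- min(cand, cap_s)
    if (new > state$required_hold_time) {
      state$last_benchmark <- state$required_hold_time
      state$required_hold_time <- new
    }
  }
  low <- day$n_trials == 0 || (!is.na(sr) && sr < reset_sr)
  if (low) {
    state$consecutive_low_days <- state$consecutive_low_days + 1L
    if (state$consecutive_low_days >= reset_days) {
      state$required_hold_time <- state$last_benchmark
      state$consecutive_low_days <- 0L
    }
  } else {
    state$consecutive_low_days <- 0L
  }
  state
}

#' Free-water deficit owed for a day
#'
#' The system tops mice up to an ideal daily intake of 1 mL; with 10 uL
#' drops that is 100 rewards. The shortfall from the previous day's earned
#' rewards is dispensed the next day as free drops on the fixed 15-minute
#' stage-1 schedule and counted toward that day's total.
#'
#' @param rewards_earned_today Number of rewards earned (drops).
#' @param daily_target_drops Target drops per day (default 100 = 1 mL).
#' @return Number of compensatory free drops owed.
#' @examples
#' free_water_deficit(60) # 40
#' @export
free_water_deficit <- function(rewards_earned_today, daily_target_drops = 100) {
  stopifnot(rewards_earned_today >= 0)
  max(0L, as.integer(daily_target_drops) - as.integer(rewards_earned_today))
}
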