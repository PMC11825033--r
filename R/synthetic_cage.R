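#' Linear parameter schedule over days
#'
#' Convenience constructor for day-varying simulator parameters: linear
#' interpolation from `from` (day 1) to `to` (day `over_days`), constant
#' beyond.
#'
#' @param from,to Values at day 1 and day `over_days`.
#' @param over_days Number of days of the ramp (default 58).
#' @return A function of the day index.
#' @export
linear_schedule <- function(from, to, over_days = 58) {
  force(from); force(to); force(over_days)
  function(day) {
    u <- pmin(pmax((day - 1) / (over_days - 1), 0), 1)
    from + u * (to - from)
  }
}

as_schedule <- function(x) {
  if (is.function(x)) return(x)
  stopifnot(is.numeric(x), length(x) == 1)
  function(day) rep(x, length(day))[seq_along(day)]
}

#' Behavioral parameters of one simulated mouse
#'
#' Defines a closed-loop agent: its hold times are drawn from the
#' two-process mixture (exponential untimed process with day-varying weight
#' `w` and rate `kappa`; Gaussian timed process tracking the current
#' requirement plus a margin), its chamber entries arrive as a Poisson
#' process with geometric bout sizes, its lever trajectories carry
#' band-limited above-10 Hz jitter of a controlled amplitude, and (optionally)
#' observing a better-performing peer's bout shifts it toward timed trials.
#'
#' @param mouse_id Mouse identifier.
#' @param genotype_label `"WT-like"` or `"HD-like"` (mapped to genotypes
#'   `"WT"` / `"HD"` in the session metadata).
#' @param w_schedule Exponential-component weight in `[0, 1]`; a constant or
#'   a function of the day (see [linear_schedule()]).
#' @param kappa_schedule Exponential rate in 1/s; constant or function of day.
#' @param timed_margin Seconds the timed (Gaussian) mean sits above the
#'   current required hold time (default 0.05).
#' @param sigma_t Timed-process SD in seconds (default 0.1).
#' @param jerk_sd SD in degrees of the band-limited (>10 Hz) trajectory
#'   noise (default 0).
#' @param entry_rate Chamber entries per hour (default 1).
#' @param bout_geom_p Geometric parameter of the bout-size distribution in
#'   `(0, 1]`; mean bout size is `1/p` (default 0.15).
#' @param influence_gain Reduction of `w` for the bout following observation
#'   of a higher-success peer bout (default 0 = no coupling).
#' @return An object of class `"agent_params"`.
#' @export
agent_params <- function(mouse_id,
                         genotype_label = c("WT-like", "HD-like"),
                         w_schedule = 0.9, kappa_schedule = 5,
                         timed_margin = 0.05, sigma_t = 0.1, jerk_sd = 0,
                         entry_rate = 1, bout_geom_p = 0.15,
                         influence_gain = 0) {
  genotype_label <- match.arg(genotype_label)
  stopifnot(timed_margin >= 0, sigma_t > 0, jerk_sd >= 0, entry_rate >= 0,
            bout_geom_p > 0, bout_geom_p <= 1, influence_gain >= 0)
  structure(list(mouse_id = mouse_id, genotype_label = genotype_label,
                 w_schedule = as_schedule(w_schedule),
                 kappa_schedule = as_schedule(kappa_schedule),
                 timed_margin = timed_margin, sigma_t = sigma_t,
                 jerk_sd = jerk_sd, entry_rate = entry_rate,
                 bout_geom_p = bout_geom_p, influence_gain = influence_gain),
            class = "agent_params")
}

#' Wild-type-like agent preset
#'
#' A learner: the untimed weight declines linearly from 0.9 to 0.4 over the
#' two-month window (the shift toward timed, requirement-tracking holds),
#' with a constant untimed rate of 5/s and trajectory jitter of 0.077 deg.
#'
#' @param mouse_id Mouse identifier.
#' @param ... Overrides passed to [agent_params()].
#' @return An [agent_params()] object.
#' @export
wt_agent <- function(mouse_id = "WT1", ...) {
  args <- list(mouse_id = mouse_id, genotype_label = "WT-like",
               w_schedule = linear_schedule(0.9, 0.4),
               kappa_schedule = 5, jerk_sd = 0.077)
  args[names(list(...))] <- list(...)
  do.call(agent_params, args)
}

#' Huntington-model-like agent preset
#'
#' A non-learner: the untimed weight stays at 0.85 while the untimed rate
#' declines slowly from 5/s to 2.5/s (hold times lengthen by stretching the
#' exponential tail rather than by forming a timed mode), with trajectory
#' jitter of 0.098 deg.
#'
#' @inheritParams wt_agent
#' @return An [agent_params()] object.
#' @export
hd_agent <- function(mouse_id = "HD1", ...) {
  args <- list(mouse_id = mouse_id, genotype_label = "HD-like",
               w_schedule = 0.85,
               kappa_schedule = linear_schedule(5, 2.5),
               jerk_sd = 0.098)
  args[names(list(...))] <- list(...)
  do.call(agent_params, args)
}

#' Simulation configuration
#'
#' @param agents List of [agent_params()].
#' @param n_days Number of simulated days (default 58, the standardized
#'   study window).
#' @param seed Integer seed; a fixed seed makes the output fully
#'   reproducible.
#' @param fs Trajectory sampling rate (400 Hz).
#' @param day0 Date string of day 1.
#' @param cage_id Cage identifier.
#' @param start_stage Initial task stage for all agents (default 1).
#' @param start_required Initial required hold time when starting in stage 2.
#' @param trajectories Synthesize per-trial trajectories (default `TRUE`;
#'   turn off for fast hold-time-only simulations).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(agents, n_days = 58, seed = 1, fs = 400,
                       day0 = "2024-01-01", cage_id = "simcage",
                       start_stage = 1, start_required = 0,
                       trajectories = TRUE) {
  stopifnot(n_days >= 1, length(agents) >= 1,
            all(vapply(agents, inherits, logical(1), "agent_params")))
  structure(list(agents = agents, n_days = as.integer(n_days),
                 seed = as.integer(seed), fs = fs, day0 = day0,
                 cage_id = cage_id, start_stage = as.integer(start_stage),
                 start_required = start_required,
                 trajectories = isTRUE(trajectories)),
            class = "sim_config")
}

#' Draw hold times from an agent's generative mixture
#'
#' With probability `w(day)` the hold comes from the untimed exponential
#' process with rate `kappa(day)`; otherwise from the timed Gaussian process
#' centred at `required + timed_margin` with SD `sigma_t`, truncated at zero.
#' Draws are clipped at the 5 s task ceiling. Uses the current RNG stream
#' (seed with `set.seed()` for reproducibility).
#'
#' @param params An [agent_params()].
#' @param day Day index (enters the schedules).
#' @param required Current required hold time in `[0, 1]` seconds.
#' @param n Number of draws.
#' @param w_override Optional weight replacing `w(day)` (used by the
#'   peer-influence coupling).
#' @return Numeric vector of `n` hold times in `[0, 5]`.
#' @export
sample_hold_time <- function(params, day, required, n = 1,
                             w_override = NULL) {
  stopifnot(required >= 0, required <= 1)
  w <- if (is.null(w_override)) params$w_schedule(day)[1] else w_override
  kap <- params$kappa_schedule(day)[1]
  untimed <- runif(n) < w
  out <- numeric(n)
  n1 <- sum(untimed)
  if (n1) out[untimed] <- rexp(n1, rate = kap)
  n2 <- n - n1
  if (n2) {
    m <- required + params$timed_margin
    lo <- pnorm(0, m, params$sigma_t)
    out[!untimed] <- qnorm(runif(n2, lo, 1), m, params$sigma_t)
  }
  pmin(out, 5)
}

# C3-continuous 7th-order smoothstep evaluated at n interior points
sstep7 <- function(n) {
  u <- seq_len(n) / (n + 1)
  ((-20 * u + 70) * u - 84) * u^2 * u^3 + 35 * u^4
}

#' Synthesize a lever trajectory with a prescribed hold time
#'
#' Builds a smooth pull profile whose residual above-10 Hz content is
#' negligible (measured leakage below 0.004 deg SD across hold lengths), so
#' that trajectory jerkiness is controlled entirely by the added noise:
#' band-limited above-10 Hz noise of sample SD `jerk_sd` is added and
#' samples are clipped to the 0--30 deg range.
#'
#' Long holds (at least 0.6 s) use a slow rise from rest to just below the
#' goal range, a smooth transition onto a plateau at `plateau` degrees, and
#' the mirrored return; transition samples falling inside the goal range are
#' counted against the plateau so the in-range run is exact. Shorter holds
#' cannot accommodate transitions both slow enough to be smooth and brief
#' enough to respect the hold duration, so they use a slow "graze" bump
#' whose peak is placed just far enough above the goal threshold that
#' exactly the required number of samples falls in range. In the noiseless
#' case [compute_hold_time()] recovers `hold_time` to within one sample
#' period. A zero hold time produces a sub-goal-range bump peaking at 5 deg.
#'
#' @param hold_time Seconds, in `[0, 5]`.
#' @param jerk_sd SD (degrees) of the added >10 Hz noise.
#' @param geom A [lever_geometry()].
#' @param fs Sampling rate (400 Hz).
#' @param plateau Plateau angle in degrees for long holds; default drawn
#'   uniformly from `[10, 20]` (uses the RNG stream).
#' @param trial_id Identifier for the returned [trajectory()].
#' @return A [trajectory()].
#' @export
synth_trajectory <- function(hold_time, jerk_sd = 0, geom = lever_geometry(),
                             fs = 400, plateau = NULL, trial_id = "synth") {
  stopifnot(hold_time >= 0, hold_time <= 5)
  if (is.null(plateau)) plateau <- runif(1, 10, 20)
  stopifnot(plateau > geom$goal_low, plateau < geom$goal_high)
  n_hold <- round(hold_time * fs)
  lo <- geom$goal_low
  base <- lo - 1  # 5 deg: below the goal range, above the pull threshold
  if (n_hold == 0) {
    up1 <- base * sstep7(140L)
    prof <- c(up1, base, rev(up1))
  } else if (n_hold < 240L) {
    # graze bump: smooth 0 -> peak -> 0 over ~(2*n_hold + 280) samples with
    # the peak amplitude tuned so exactly n_hold samples sit in range
    half <- ceiling((2 * n_hold + 280) / 2)
    b <- c(sstep7(half), rev(sstep7(half)))
    b_lo <- lo; b_hi <- geom$goal_high
    for (it in 1:50) {
      bm <- (b_lo + b_hi) / 2
      if (sum(bm * b >= lo) >= n_hold) b_hi <- bm else b_lo <- bm
    }
    prof <- b_hi * b
  } else {
    t1 <- 100L
    up1 <- base * sstep7(t1)
    t2 <- 160L
    repeat {
      up2 <- base + (plateau - base) * sstep7(t2)
      m <- sum(up2 >= lo)
      if (2 * m <= n_hold || t2 <= 1L) break
      t2 <- max(1L, t2 - 8L)
    }
    prof <- c(up1, up2, rep(plateau, n_hold - 2 * m), rev(up2), rev(up1))
  }
  if (jerk_sd > 0) {
    e <- hp_zerophase(rnorm(length(prof)), fs)
    s <- sd(e)
    if (s > 0) prof <- prof + e * (jerk_sd / s)
  }
  trajectory(trial_id, pmin(pmax(prof, 0), 30), fs = fs)
}

trailing_sr <- function(outcomes, k = 30) {
  n <- length(outcomes)
  if (n < 10) return(0.5)
  mean(outcomes[max(1, n - k + 1):n])
}

#' Simulate a multi-animal home cage in closed loop with the scheduler
#'
#' Agent-based generator of complete session logs. Each day, every agent's
#' chamber entries arrive as a Poisson process at its entry rate; each entry
#' holds a geometric number of trials spaced 10--60 s apart. Every trial
#' draws a hold time from the agent's generative mixture, optionally
#' synthesizes a matching trajectory, and is classified by the task logic
#' against the agent's current scheduler state. At each midnight the
#' habituation-stage advancement and the required-hold-time update run
#' exactly as in the live task, so requirement trajectories emerge from the
#' interaction between agent behavior and the scheduler. With a positive
#' `influence_gain`, an agent starting a bout within 5 minutes of a
#' higher-success peer bout of 10+ trials has its untimed weight reduced for
#' that bout.
#'
#' The trial records store the sampled (grid-quantised) hold time, which the
#' synthesized trajectory reproduces to within one sample in the noiseless
#' case; classification uses the recorded value.
#'
#' @param cfg A [sim_config()].
#' @return A validated [session_log()]. Attribute `scheduler_trace` is a
#'   data frame with one row per mouse-day (`day`, `mouse_id`, `stage`,
#'   `required_hold_time` in force after that midnight's update, `n_trials`,
#'   `n_success`, `success_rate`, `free_drops`).
#' @examples
#' cfg <- sim_config(list(wt_agent(), hd_agent()), n_days = 2, seed = 1,
#'                   trajectories = FALSE)
#' log <- simulate_cage(cfg)
#' log
#' @export
simulate_cage <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  agents <- cfg$agents
  ids <- vapply(agents, `[[`, character(1), "mouse_id")
  names(agents) <- ids
  states <- lapply(ids, function(m) {
    scheduler_state(m, stage = cfg$start_stage,
                    required_hold_time = cfg$start_required,
                    last_benchmark = cfg$start_required)
  })
  names(states) <- ids
  outcomes <- lapply(states, function(s) logical())      # per-agent history
  pending <- lapply(states, function(s) NULL)  # trials awaiting a midnight
  prev_exit <- stats::setNames(rep(-Inf, length(ids)), ids)
  recent_bouts <- data.frame(mouse_id = character(), t_end = numeric(),
                             n = integer(), sr = numeric())
  trials <- list(); entries <- list(); trajs <- list(); trace <- list()
  trial_n <- 0L; entry_n <- 0L
  geom <- lever_geometry()

  for (d in seq_len(cfg$n_days)) {
    # entry candidates for the day, all agents, merged in time order
    cand <- do.call(rbind, lapply(ids, function(m) {
      ne <- rpois(1, agents[[m]]$entry_rate * 24)
      if (ne == 0) return(NULL)
      data.frame(mouse_id = m,
                 t = (d - 1) * 86400 + sort(runif(ne, 0, 86400)))
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand$t), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        m <- cand$mouse_id[r]
        ag <- agents[[m]]
        st <- max(cand$t[r], prev_exit[[m]] + 1)
        k <- rgeom(1, ag$bout_geom_p) + 1L
        w_eff <- NULL
        if (ag$influence_gain > 0) {
          rb <- recent_bouts[recent_bouts$mouse_id != m &
                               recent_bouts$t_end >= st - 300 &
                               recent_bouts$t_end <= st, , drop = FALSE]
          if (nrow(rb) && any(rb$sr > trailing_sr(outcomes[[m]]))) {
            w_eff <- max(0, ag$w_schedule(d)[1] - ag$influence_gain)
          }
        }
        tt <- st + runif(1, 2, 10) + c(0, cumsum(runif(k - 1, 10, 60)))
        state <- states[[m]]
        h <- sample_hold_time(ag, d, state$required_hold_time, n = k,
                              w_override = w_eff)
        h <- round(h * cfg$fs) / cfg$fs
        succ <- if (state$stage == 1L) rep(TRUE, k) else
          h >= state$required_hold_time
        entry_n <- entry_n + 1L
        eid <- sprintf("E%06d", entry_n)
        tids <- sprintf("T%06d", trial_n + seq_len(k))
        trial_n <- trial_n + k
        refs <- rep(NA_character_, k)
        if (cfg$trajectories) {
          for (i in seq_len(k)) {
            trajs[[tids[i]]] <- synth_trajectory(h[i], ag$jerk_sd, geom,
                                                 cfg$fs, trial_id = tids[i])
          }
          refs <- tids
        }
        chunk <- data.frame(
          trial_id = tids, mouse_id = m, entry_id = eid, t_start = tt,
          stage = state$stage, required_hold_time = state$required_hold_time,
          hold_time = h, success = succ, trajectory_ref = refs,
          stringsAsFactors = FALSE)
        trials[[length(trials) + 1L]] <- chunk
        pending[[m]] <- c(pending[[m]], list(chunk))
        t_exit <- tt[k] + runif(1, 5, 20)
        entries[[length(entries) + 1L]] <- data.frame(
          entry_id = eid, mouse_id = m, t_enter = st, t_exit = t_exit,
          stringsAsFactors = FALSE)
        prev_exit[[m]] <- t_exit
        outcomes[[m]] <- c(outcomes[[m]], succ)
        if (k >= 10L) {
          recent_bouts <- rbind(recent_bouts, data.frame(
            mouse_id = m, t_end = tt[k], n = k,
            sr = mean(succ[seq_len(min(10L, k))])))
          if (nrow(recent_bouts) > 200) {
            recent_bouts <- tail(recent_bouts, 100)
          }
        }
      }
    }
    # midnight: scheduler updates from the completed day
    for (m in ids) {
      tr_m <- if (length(pending[[m]])) do.call(rbind, pending[[m]]) else NULL
      day_tr <- NULL
      if (!is.null(tr_m)) {
        in_day <- day_of(tr_m$t_start) == d
        day_tr <- tr_m[in_day, , drop = FALSE]
        carry <- tr_m[day_of(tr_m$t_start) > d, , drop = FALSE]
        pending[[m]] <- if (nrow(carry)) list(carry) else NULL
      }
      n_day <- if (is.null(day_tr)) 0L else nrow(day_tr)
      state <- states[[m]]
      if (state$stage == 1L) {
        ds <- day_summary(m, d,
                          if (n_day) day_tr$hold_time else numeric(),
                          if (n_day) day_tr$success else logical())
        state <- advance_stage(ds, state)
      } else {
        s2 <- if (n_day) day_tr[day_tr$stage == 2L, , drop = FALSE] else NULL
        ds <- day_summary(m, d,
                          if (!is.null(s2) && nrow(s2)) s2$hold_time else numeric(),
                          if (!is.null(s2) && nrow(s2)) s2$success else logical())
        state <- update_required_hold_time(ds, state)
      }
      states[[m]] <- state
      n_succ <- if (n_day) sum(day_tr$success) else 0L
      trace[[length(trace) + 1L]] <- data.frame(
        day = d, mouse_id = m, stage = state$stage,
        required_hold_time = state$required_hold_time,
        n_trials = n_day, n_success = n_succ,
        success_rate = if (n_day) n_succ / n_day else NA_real_,
        free_drops = free_water_deficit(n_succ), stringsAsFactors = FALSE)
    }
  }
  trials_df <- if (length(trials)) do.call(rbind, trials) else
    data.frame(trial_id = character(), mouse_id = character(),
               entry_id = character(), t_start = numeric(), stage = integer(),
               required_hold_time = numeric(), hold_time = numeric(),
               success = logical(), trajectory_ref = character())
  entries_df <- if (length(entries)) do.call(rbind, entries) else
    data.frame(entry_id = character(), mouse_id = character(),
               t_enter = numeric(), t_exit = numeric())
  geno <- vapply(agents, function(a) {
    if (a$genotype_label == "WT-like") "WT" else "HD"
  }, character(1))
  log <- session_log(trials_df, entries_df, trajs,
                     metadata = list(cage_id = cfg$cage_id, day0 = cfg$day0,
                                     genotypes = geno))
  attr(log, "scheduler_trace") <- do.call(rbind, trace)
  log
}
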