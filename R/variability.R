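#' Dynamic time warping distance between two sequences
#'
#' Classic dynamic-programming DTW: both sequences are stretched onto a
#' common set of time instants (monotone alignment with unit match/insert/
#' delete steps, no window constraint) so as to minimise the summed pointwise
#' Euclidean distance (absolute difference for scalar samples). Note DTW is
#' symmetric and `dtw(a, a) = 0`, but it is not a metric: the triangle
#' inequality can fail.
#'
#' @param a,b Non-empty numeric vectors (an empty input is an error).
#' @return Minimal cumulative alignment cost (`>= 0`).
#' @examples
#' dtw_distance(c(0, 1, 2), c(0, 2))  # 1
#' @export
dtw_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("dtw_distance: empty sequence")
  .dtw_cost(a, b)
}

zscore <- function(v) {
  mu <- mean(v, na.rm = TRUE)
  s <- sd(v, na.rm = TRUE)
  if (!is.finite(s) || s < 1e-12) {
    return(structure(rep(NA_real_, length(v)), degenerate = TRUE))
  }
  structure((v - mu) / s, degenerate = FALSE)
}

mouse_trials <- function(log, mouse_id, max_day = NULL) {
  tr <- log$trials[log$trials$mouse_id == mouse_id, , drop = FALSE]
  tr <- tr[order(tr$t_start), , drop = FALSE]
  if (!is.null(max_day) && nrow(tr)) {
    tr <- tr[day_of(tr$t_start) <= max_day, , drop = FALSE]
  }
  rownames(tr) <- NULL
  tr
}

# raw consecutive-pair DTW distances along a mouse's ordered trial table;
# element i is the distance between trial i and trial i-1 (NA at i = 1 or
# when either trajectory is unavailable). `idx` restricts computation to the
# requested positions, which keeps the event-aligned analyses cheap.
consecutive_dtw_raw <- function(log, tr, idx = NULL) {
  n <- nrow(tr)
  d <- rep(NA_real_, n)
  if (n < 2) return(d)
  if (is.null(idx)) idx <- 2:n
  idx <- sort(unique(idx[idx >= 2 & idx <= n]))
  get <- function(i) {
    ref <- tr$trajectory_ref[i]
    if (is.na(ref)) return(NULL)
    log$trajectories[[ref]]
  }
  for (i in idx) {
    prev <- get(i - 1L)
    curr <- get(i)
    if (!is.null(prev) && !is.null(curr)) {
      d[i] <- dtw_distance(prev$angle, curr$angle)
    }
  }
  d
}

#' Trajectory variability between consecutive trials
#'
#' DTW distance between each temporally adjacent pair of a mouse's trial
#' trajectories (regardless of chamber-entry boundaries), z-scored over the
#' analysed trials of that mouse. A constant-trajectory mouse yields raw
#' distances of zero; the z-scores are then undefined and the result is
#' flagged degenerate.
#'
#' @param log A [session_log()].
#' @param mouse_id Mouse to analyse.
#' @param max_day Restrict to the first `max_day` days (`NULL` = all).
#' @return Data frame with columns `trial_id`, `prev_trial_id`, `t_start`,
#'   `dtw` (raw), `z`; fewer than 2 trials give an empty frame. Attribute
#'   `degenerate` is `TRUE` when the raw distances have no spread.
#' @export
consecutive_dtw <- function(log, mouse_id, max_day = NULL) {
  stopifnot(inherits(log, "session_log"))
  tr <- mouse_trials(log, mouse_id, max_day)
  if (nrow(tr) < 2) {
    return(structure(data.frame(trial_id = character(),
                                prev_trial_id = character(),
                                t_start = numeric(), dtw = numeric(),
                                z = numeric()),
                     degenerate = FALSE))
  }
  d <- consecutive_dtw_raw(log, tr)
  keep <- which(!is.na(d))
  z <- zscore(d[keep])
  out <- data.frame(trial_id = tr$trial_id[keep],
                    prev_trial_id = tr$trial_id[keep - 1L],
                    t_start = tr$t_start[keep],
                    dtw = d[keep], z = as.numeric(z))
  structure(out, degenerate = attr(z, "degenerate"))
}

#' Moving standard deviation of hold times
#'
#' Local hold-time variability over a centred sliding window (default 5
#' trials); windows are truncated ("shrunk") at the series edges. The raw
#' series is z-scored over the analysed trials.
#'
#' @param hold_times Ordered numeric vector of hold times.
#' @param window Window length in trials (default 5).
#' @return Data frame with columns `raw` and `z` (one row per trial).
#'   Attribute `degenerate` flags a spread-free raw series.
#' @examples
#' moving_std_holdtimes(c(0.1, 0.2, 0.3, 0.4, 0.5))$raw[3]  # sd of all 5
#' @export
moving_std_holdtimes <- function(hold_times, window = 5) {
  x <- as.numeric(hold_times)
  n <- length(x)
  half <- (window - 1) %/% 2
  raw <- vapply(seq_len(n), function(i) {
    idx <- max(1L, i - half):min(n, i + half)
    if (length(idx) < 2) return(0)
    sd(x[idx])
  }, numeric(1))
  z <- zscore(raw)
  structure(data.frame(raw = raw, z = as.numeric(z)),
            degenerate = attr(z, "degenerate"))
}

#' Detect window bouts (>= `min_trials` trials within a time window)
#'
#' Greedy left-to-right scan over a mouse's trial times: a bout starts at the
#' first trial `t` such that trials `t ... t+min_trials-1` span at most
#' `window_s` seconds, and extends while each added trial keeps the trailing
#' `min_trials`-trial span within `window_s`; candidates are consumed
#' greedily without overlap.
#'
#' @param t Sorted numeric vector of trial times (s).
#' @param min_trials Minimum trials per bout (default 10).
#' @param window_s Window length in seconds (default 300).
#' @return Data frame with columns `start`, `end` (indices into `t`).
#' @export
find_window_bouts <- function(t, min_trials = 10, window_s = 300) {
  n <- length(t)
  starts <- integer(); ends <- integer()
  i <- 1L
  while (i <= n - min_trials + 1L) {
    if (t[i + min_trials - 1L] - t[i] <= window_s) {
      j <- i + min_trials - 1L
      while (j + 1L <= n && t[j + 1L] - t[j + 2L - min_trials] <= window_s) {
        j <- j + 1L
      }
      starts <- c(starts, i); ends <- c(ends, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  data.frame(start = starts, end = ends)
}

#' Trial-aligned response to required-hold-time increases
#'
#' For every upward change in a mouse's required hold time (the midnight
#' scheduler updates), extracts the 5 trials before and 15 trials after the
#' change (by trial index, crossing entry boundaries) and tabulates per-offset
#' success, consecutive-trial DTW and moving-SD of hold times; the two
#' variability measures are z-scored within mouse over the analysed trials.
#' Mice that never left their initial hold time have no events and yield an
#' empty result.
#'
#' @param log A [session_log()].
#' @param mouse_id Mouse to analyse.
#' @param before,after Window sizes in trials (defaults 5 and 15).
#' @param max_day Restrict to the first `max_day` days (default 58, the
#'   standardized window; `NULL` = all).
#' @return Data frame with columns `event_id`, `mouse_id`, `position`
#'   (-before..-1, 1..after), `t_event`, `success`, `dtw_z`, `movstd_z`.
#'   Events lacking a full window are skipped.
#' @export
align_to_holdtime_change <- function(log, mouse_id, before = 5, after = 15,
                                     max_day = 58) {
  stopifnot(inherits(log, "session_log"))
  tr <- mouse_trials(log, mouse_id, max_day)
  empty <- data.frame(event_id = character(), mouse_id = character(),
                      position = integer(), t_event = numeric(),
                      success = integer(), dtw_z = numeric(),
                      movstd_z = numeric())
  n <- nrow(tr)
  if (n < before + after) return(empty)
  ev <- which(diff(tr$required_hold_time) > 0) + 1L
  ev <- ev[ev - before >= 1L & ev + after - 1L <= n]
  if (!length(ev)) return(empty)
  need <- unique(unlist(lapply(ev, function(i) (i - before):(i + after - 1L))))
  d_raw <- consecutive_dtw_raw(log, tr, idx = need)
  ms_raw <- moving_std_holdtimes(tr$hold_time)$raw
  pos <- c(-(before:1), seq_len(after))
  rows <- do.call(rbind, lapply(seq_along(ev), function(k) {
    i <- ev[k]
    idx <- c((i - before):(i - 1L), i:(i + after - 1L))
    data.frame(event_id = sprintf("%s_ev%02d", mouse_id, k),
               mouse_id = mouse_id, position = pos,
               t_event = tr$t_start[i],
               success = as.integer(tr$success[idx]),
               dtw_raw = d_raw[idx], movstd_raw = ms_raw[idx],
               stringsAsFactors = FALSE)
  }))
  # z-score within mouse over the analysed trials
  rows$dtw_z <- as.numeric(zscore(rows$dtw_raw))
  rows$movstd_z <- as.numeric(zscore(rows$movstd_raw))
  rows[, c("event_id", "mouse_id", "position", "t_event", "success",
           "dtw_z", "movstd_z")]
}

#' Trajectory variability across the first trials of extended bouts
#'
#' Over bouts of at least `min_trials` trials within a `window_s` window
#' (see [find_window_bouts()]), tabulates the consecutive-trial DTW z-score
#' at within-bout positions 1..`min_trials`, averaged over bouts. Position
#' `p`'s value is the distance between bout trial `p` and the mouse's
#' preceding trial, so position 1 pairs with the last pre-bout trial (missing
#' when the bout opens the record).
#'
#' @inheritParams align_to_holdtime_change
#' @param min_trials,window_s Bout criterion (defaults 10 trials in 300 s).
#' @return Data frame with columns `position` (1..`min_trials`), `mean_dtw_z`,
#'   `n_bouts`; attribute `per_bout` holds the per-bout long table and
#'   attribute `degenerate` flags spread-free distances.
#' @export
bout_variability <- function(log, mouse_id, min_trials = 10, window_s = 300,
                             max_day = 58) {
  stopifnot(inherits(log, "session_log"))
  tr <- mouse_trials(log, mouse_id, max_day)
  res <- data.frame(position = seq_len(min_trials), mean_dtw_z = NA_real_,
                    n_bouts = 0L)
  if (nrow(tr) < min_trials) return(structure(res, degenerate = FALSE))
  bouts <- find_window_bouts(tr$t_start, min_trials, window_s)
  if (!nrow(bouts)) return(structure(res, degenerate = FALSE))
  need <- unique(unlist(lapply(bouts$start, function(s) s + seq_len(min_trials) - 1L)))
  d_raw <- consecutive_dtw_raw(log, tr, idx = need)
  long <- do.call(rbind, lapply(seq_len(nrow(bouts)), function(b) {
    idx <- bouts$start[b] + seq_len(min_trials) - 1L
    pair_with_prev <- idx  # d_raw[i] = distance(trial i-1, trial i)
    data.frame(bout = b, position = seq_len(min_trials),
               dtw_raw = d_raw[pair_with_prev])
  }))
  z <- zscore(long$dtw_raw)
  long$dtw_z <- as.numeric(z)
  agg <- tapply(long$dtw_z, long$position, mean, na.rm = TRUE)
  cnt <- tapply(!is.na(long$dtw_z), long$position, sum)
  res$mean_dtw_z <- as.numeric(agg[as.character(res$position)])
  res$n_bouts <- as.integer(cnt[as.character(res$position)])
  structure(res, per_bout = long, degenerate = attr(z, "degenerate"))
}

#' Trajectory variability within same-outcome trial runs
#'
#' Finds runs of `run_len` (5) consecutive all-successful or all-failed
#' trials whose first-to-last span is at most `span_s` (150 s); longer
#' same-outcome stretches contribute only their first `run_len`-trial window
#' (no double counting). For each run the `run_len - 1` consecutive-pair DTW
#' distances are z-scored (within mouse, over the analysed pairs) and
#' averaged per pair position across runs.
#'
#' @inheritParams align_to_holdtime_change
#' @param outcome `"success"` or `"failure"`.
#' @param run_len Run length in trials (default 5).
#' @param span_s Maximum first-to-last span in seconds (default 150).
#' @return Data frame with columns `position` (1..`run_len - 1`),
#'   `mean_dtw_z`, `n_runs`; attribute `per_run` has the long table.
#' @export
outcome_run_variability <- function(log, mouse_id,
                                    outcome = c("success", "failure"),
                                    run_len = 5, span_s = 150, max_day = 58) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(log, "session_log"))
  tr <- mouse_trials(log, mouse_id, max_day)
  res <- data.frame(position = seq_len(run_len - 1L), mean_dtw_z = NA_real_,
                    n_runs = 0L)
  if (nrow(tr) < run_len) return(structure(res, degenerate = FALSE))
  want <- if (outcome == "success") tr$success else !tr$success
  r <- rle(want)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_starts <- integer()
  for (k in which(r$values & r$lengths >= run_len)) {
    s <- starts[k]
    if (tr$t_start[s + run_len - 1L] - tr$t_start[s] <= span_s) {
      run_starts <- c(run_starts, s)  # first window of the maximal run only
    }
  }
  if (!length(run_starts)) return(structure(res, degenerate = FALSE))
  need <- unique(unlist(lapply(run_starts, function(s) s + seq_len(run_len - 1L))))
  d_raw <- consecutive_dtw_raw(log, tr, idx = need)
  long <- do.call(rbind, lapply(seq_along(run_starts), function(q) {
    s <- run_starts[q]
    data.frame(run = q, position = seq_len(run_len - 1L),
               dtw_raw = d_raw[s + seq_len(run_len - 1L)])
  }))
  z <- zscore(long$dtw_raw)
  long$dtw_z <- as.numeric(z)
  agg <- tapply(long$dtw_z, long$position, mean, na.rm = TRUE)
  cnt <- tapply(!is.na(long$dtw_z), long$position, sum)
  res$mean_dtw_z <- as.numeric(agg[as.character(res$position)])
  res$n_runs <- as.integer(cnt[as.character(res$position)])
  structure(res, per_run = long, degenerate = attr(z, "degenerate"))
}
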