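#' @noRd
hp_coefs <- function(fs = 400) {
  key <- paste0("hp", fs)
  co <- .leverlog_env[[key]]
  if (is.null(co)) {
    # minimum-order Chebyshev-I high-pass: passband edge 10 Hz (0.1 dB),
    # stopband edge 5 Hz at 60 dB attenuation
    ord <- signal::cheb1ord(10 / (fs / 2), 5 / (fs / 2), Rp = 0.1, Rs = 60)
    flt <- signal::cheby1(ord)
    co <- list(b = flt$b, a = flt$a,
               nf = max(length(flt$a), length(flt$b)) - 1L)
    .leverlog_env[[key]] <- co
  }
  co
}

# one causal pass, initialised at the DC steady state (past inputs = x[1],
# past outputs = 0: exact for a high-pass, whose DC gain is 0)
hp_pass <- function(co, x) {
  as.numeric(signal::filter(co$b, co$a, x,
                            init.x = rep(x[1], co$nf),
                            init.y = rep(0, co$nf)))
}

#' Zero-phase 10 Hz high-pass filter
#'
#' Isolates the above-10 Hz component of a lever trajectory, the band that
#' carries movement jerkiness/tremor. The filter is a minimum-order
#' Chebyshev-I high-pass (passband edge 10 Hz, stopband edge 5 Hz, at least
#' 60 dB stopband attenuation at 400 Hz sampling; order 8), applied
#' forward-backward with odd-reflection padding and DC steady-state
#' initial conditions so the result is delay-free and edge transients are
#' suppressed. Output length equals input length.
#'
#' Trajectories shorter than `min_samples` (20 samples = 0.05 s) are too
#' short to filter meaningfully and yield `NULL` (an exclusion signal, not an
#' error).
#'
#' @param traj A [trajectory()] or numeric vector of angles (degrees).
#' @param fs Sampling rate in Hz (default 400).
#' @param min_samples Minimum trajectory length (default 20).
#' @return Numeric vector of filtered angles, or `NULL` if too short.
#' @examples
#' y <- highpass_10hz(sin(2 * pi * 2 * (0:799) / 400))  # 2 Hz: removed
#' sqrt(mean(y^2))
#' @export
highpass_10hz <- function(traj, fs = 400, min_samples = 20) {
  x <- if (inherits(traj, "trajectory")) {
    fs <- traj$fs
    traj$angle
  } else as.numeric(traj)
  if (length(x) < min_samples) return(NULL)
  hp_zerophase(x, fs)
}

# zero-phase high-pass core: odd-reflection padding + forward-backward pass
hp_zerophase <- function(x, fs = 400) {
  n <- length(x)
  if (n < 2) return(rep(0, n))
  co <- hp_coefs(fs)
  npad <- min(400L, n - 1L)
  xe <- c(2 * x[1] - x[(npad + 1):2], x,
          2 * x[n] - x[(n - 1):(n - npad)])
  y <- rev(hp_pass(co, rev(hp_pass(co, xe))))
  y[(npad + 1):(npad + n)]
}

#' Jerkiness of a single trial
#'
#' Jerkiness is the standard deviation (denominator `n - 1`) of the
#' above-10 Hz component of the lever trajectory. Trials shorter than 20
#' samples (0.05 s) are excluded as non-representative of the intended
#' movement.
#'
#' @param traj A [trajectory()].
#' @return A list with `trial_id`, `jerkiness` (degrees; `NA` if excluded),
#'   `excluded` (logical) and `reason`.
#' @export
trial_jerkiness <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  y <- highpass_10hz(traj)
  if (is.null(y)) {
    return(list(trial_id = traj$trial_id, jerkiness = NA_real_,
                excluded = TRUE, reason = "shorter than 20 samples"))
  }
  list(trial_id = traj$trial_id, jerkiness = sd(y),
       excluded = FALSE, reason = NA_character_)
}

#' Daily mean jerkiness for one mouse
#'
#' Averages [trial_jerkiness()] over the non-excluded trials of each day.
#'
#' @param log A [session_log()] whose trials carry trajectory references.
#' @param mouse_id Mouse to analyse.
#' @param days Integer vector of day indices (default: all days observed for
#'   the mouse; pass `1:58` for the standardized two-month window).
#' @return Data frame with columns `day`, `mean_jerkiness` (`NA` when no
#'   usable trials), `n_trials`, `n_excluded`.
#' @export
daily_jerkiness <- function(log, mouse_id, days = NULL) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials[log$trials$mouse_id == mouse_id, , drop = FALSE]
  if (is.null(days)) {
    days <- if (nrow(tr)) seq_len(max(day_of(tr$t_start))) else integer()
  }
  res <- data.frame(day = as.integer(days), mean_jerkiness = NA_real_,
                    n_trials = 0L, n_excluded = 0L)
  if (!nrow(tr)) return(res)
  tr$day <- day_of(tr$t_start)
  jk <- vapply(tr$trajectory_ref, function(ref) {
    if (is.na(ref) || is.null(log$trajectories[[ref]])) return(NA_real_)
    r <- trial_jerkiness(log$trajectories[[ref]])
    if (r$excluded) NA_real_ else r$jerkiness
  }, numeric(1), USE.NAMES = FALSE)
  for (i in seq_along(days)) {
    sel <- tr$day == days[i]
    res$n_trials[i] <- sum(sel)
    v <- jk[sel]
    res$n_excluded[i] <- sum(sel) - sum(!is.na(v))
    if (any(!is.na(v))) res$mean_jerkiness[i] <- mean(v, na.rm = TRUE)
  }
  res
}
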