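#' Daily engagement metrics for one mouse
#'
#' Per-day counts of trials and chamber entries, average time spent in the
#' chamber per entry, trials per entry and daily success rate. Days without
#' activity report zero counts and missing means. Entries are assigned to the
#' day of `t_enter`, trials to the day of `t_start`.
#'
#' @param log A [session_log()].
#' @param mouse_id Mouse to analyse.
#' @param days Day indices to report (default `1:58`, the standardized
#'   two-month window).
#' @return Data frame with columns `mouse_id`, `day`, `n_trials`,
#'   `n_entries`, `mean_time_in_chamber_s`, `trials_per_entry`,
#'   `success_rate`.
#' @export
daily_engagement <- function(log, mouse_id, days = 1:58) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials[log$trials$mouse_id == mouse_id, , drop = FALSE]
  en <- log$entries[log$entries$mouse_id == mouse_id, , drop = FALSE]
  tday <- day_of(tr$t_start)
  eday <- day_of(en$t_enter)
  out <- data.frame(mouse_id = mouse_id, day = as.integer(days),
                    n_trials = 0L, n_entries = 0L,
                    mean_time_in_chamber_s = NA_real_,
                    trials_per_entry = NA_real_, success_rate = NA_real_)
  for (i in seq_along(days)) {
    d <- days[i]
    ti <- tday == d
    ei <- eday == d
    out$n_trials[i] <- sum(ti)
    out$n_entries[i] <- sum(ei)
    if (any(ei)) {
      out$mean_time_in_chamber_s[i] <- mean(en$t_exit[ei] - en$t_enter[ei])
      out$trials_per_entry[i] <- sum(ti) / sum(ei)
    }
    if (any(ti)) out$success_rate[i] <- mean(tr$success[ti])
  }
  out
}

#' Entry-bout sizes and per-size success rates
#'
#' An entry bout is the sequence of consecutive trials performed within one
#' chamber entry. Returns the histogram of bout sizes (entries with zero
#' trials are not bouts) and the mean success rate over trials belonging to
#' bouts of each size. Sizes at or above `size_cap` are pooled into the top
#' bin.
#'
#' @param log A [session_log()].
#' @param mouse_id Mouse to analyse, or `NULL` for all mice pooled.
#' @param size_cap Top histogram bin; larger bouts are pooled here
#'   (default 14).
#' @return Data frame with columns `size` (1..`size_cap`; the last row pools
#'   `>= size_cap`), `count` (bouts), `n_trials`, `success_rate`. Attribute
#'   `sizes` carries the raw per-entry bout sizes.
#' @export
entry_bout_sizes <- function(log, mouse_id = NULL, size_cap = 14) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  if (!is.null(mouse_id)) tr <- tr[tr$mouse_id == mouse_id, , drop = FALSE]
  out <- data.frame(size = seq_len(size_cap), count = 0L, n_trials = 0L,
                    success_rate = NA_real_)
  if (!nrow(tr)) return(structure(out, sizes = integer()))
  sizes <- table(tr$entry_id)
  bout_of_trial <- as.integer(sizes[tr$entry_id])
  raw_sizes <- as.integer(sizes)
  binned_trial <- pmin(bout_of_trial, size_cap)
  binned_bout <- pmin(raw_sizes, size_cap)
  for (s in seq_len(size_cap)) {
    out$count[s] <- sum(binned_bout == s)
    sel <- binned_trial == s
    out$n_trials[s] <- sum(sel)
    if (any(sel)) out$success_rate[s] <- mean(tr$success[sel])
  }
  structure(out, sizes = raw_sizes)
}
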