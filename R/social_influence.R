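# bouts for one mouse as a table with times and success rates
mouse_bouts <- function(log, mouse_id, min_trials, window_s, sr_first_n) {
  tr <- mouse_trials(log, mouse_id)
  if (nrow(tr) < min_trials) {
    return(data.frame(start = integer(), end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      n = integer(), sr = numeric()))
  }
  b <- find_window_bouts(tr$t_start, min_trials, window_s)
  if (!nrow(b)) {
    return(data.frame(start = integer(), end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      n = integer(), sr = numeric()))
  }
  b$t_start <- tr$t_start[b$start]
  b$t_end <- tr$t_start[b$end]
  b$n <- b$end - b$start + 1L
  b$sr <- vapply(seq_len(nrow(b)), function(i) {
    idx <- b$start[i]:b$end[i]
    if (sr_first_n > 0) idx <- idx[seq_len(min(sr_first_n, length(idx)))]
    mean(tr$success[idx])
  }, numeric(1))
  b
}

#' Detect follower-influencer motifs
#'
#' Scans every ordered pair of mice for the three-bout social motif: the
#' follower performs a bout of at least `min_trials` trials within a
#' `bout_window_s` window (baseline), the influencer performs a similar bout
#' starting within `max_gap_s` of the baseline's end, and the follower
#' returns for a third bout within `max_gap_s` of the influencer's end. The
#' influencer is classed `"good"` if its bout success rate exceeds the
#' follower's baseline, else `"bad"`, and the follower's relative change in
#' success is `delta_success = (sr_after - sr_baseline) / sr_baseline`
#' (`NA` when the baseline rate is zero). Overlapping candidates are consumed
#' greedily in time order without reusing a bout within a pair.
#'
#' @param log A [session_log()] with at least 2 mice for a non-empty result.
#' @param min_trials Minimum trials per bout (default 10).
#' @param bout_window_s Bout time window in seconds (default 300).
#' @param max_gap_s Maximum inter-bout gap in seconds (default 300).
#' @param sr_first_n Number of leading trials defining a bout's success rate
#'   (default 10, the bout criterion size; `0` uses the full run).
#' @return Data frame, one row per motif: `follower_id`, `influencer_id`,
#'   bout times (`t_b1_start` ... `t_b3_end`), bout sizes (`n_b1` ...),
#'   `sr_baseline`, `sr_influencer`, `sr_after`, `influencer_class`,
#'   `delta_success`.
#' @seealso [find_controls()], [influence_summary()]
#' @export
find_motifs <- function(log, min_trials = 10, bout_window_s = 300,
                        max_gap_s = 300, sr_first_n = 10) {
  stopifnot(inherits(log, "session_log"))
  mice <- unique(log$trials$mouse_id)
  empty <- data.frame(follower_id = character(), influencer_id = character(),
                      t_b1_start = numeric(), t_b1_end = numeric(),
                      t_b2_start = numeric(), t_b2_end = numeric(),
                      t_b3_start = numeric(), t_b3_end = numeric(),
                      n_b1 = integer(), n_b2 = integer(), n_b3 = integer(),
                      sr_baseline = numeric(), sr_influencer = numeric(),
                      sr_after = numeric(), influencer_class = character(),
                      delta_success = numeric())
  if (length(mice) < 2) return(empty)
  bouts <- lapply(stats::setNames(mice, mice), mouse_bouts, log = log,
                  min_trials = min_trials, window_s = bout_window_s,
                  sr_first_n = sr_first_n)
  rows <- list()
  for (f in mice) for (inf in setdiff(mice, f)) {
    fb <- bouts[[f]]; ib <- bouts[[inf]]
    if (!nrow(fb) || !nrow(ib)) next
    used_f <- rep(FALSE, nrow(fb))
    used_i <- rep(FALSE, nrow(ib))
    for (j in seq_len(nrow(ib))) {
      if (used_i[j]) next
      # latest unused follower bout ending at/before the influencer bout
      # starts, within the gap
      cand1 <- which(!used_f & fb$t_end <= ib$t_start[j] &
                       ib$t_start[j] - fb$t_end <= max_gap_s)
      if (!length(cand1)) next
      b1 <- cand1[length(cand1)]
      # earliest unused follower bout starting at/after the influencer bout
      # ends, within the gap
      cand3 <- which(!used_f & fb$t_start >= ib$t_end[j] &
                       fb$t_start - ib$t_end[j] <= max_gap_s)
      cand3 <- setdiff(cand3, b1)
      if (!length(cand3)) next
      b3 <- cand3[1]
      used_f[c(b1, b3)] <- TRUE
      used_i[j] <- TRUE
      sr_b <- fb$sr[b1]; sr_i <- ib$sr[j]; sr_a <- fb$sr[b3]
      rows[[length(rows) + 1L]] <- data.frame(
        follower_id = f, influencer_id = inf,
        t_b1_start = fb$t_start[b1], t_b1_end = fb$t_end[b1],
        t_b2_start = ib$t_start[j], t_b2_end = ib$t_end[j],
        t_b3_start = fb$t_start[b3], t_b3_end = fb$t_end[b3],
        n_b1 = fb$n[b1], n_b2 = ib$n[j], n_b3 = fb$n[b3],
        sr_baseline = sr_b, sr_influencer = sr_i, sr_after = sr_a,
        influencer_class = if (sr_i > sr_b) "good" else "bad",
        delta_success = if (sr_b > 0) (sr_a - sr_b) / sr_b else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$t_b2_start, out$follower_id, out$influencer_id), ,
      drop = FALSE]
}

#' Detect solitary two-bout control patterns
#'
#' The no-influencer control for [find_motifs()]: a single mouse performs two
#' qualifying bouts separated by a 5--15 minute timeout, with no other mouse
#' performing a qualifying bout in the gap. `delta_success` compares the two
#' bouts exactly as the motif statistic does.
#'
#' @inheritParams find_motifs
#' @param gap_min_s,gap_max_s Allowed gap between the bouts in seconds
#'   (defaults 300 and 900).
#' @return Data frame with one row per control event: `mouse_id`, bout times
#'   and sizes, `sr_bout1`, `sr_bout2`, `delta_success`.
#' @export
find_controls <- function(log, min_trials = 10, bout_window_s = 300,
                          gap_min_s = 300, gap_max_s = 900, sr_first_n = 10) {
  stopifnot(inherits(log, "session_log"))
  mice <- unique(log$trials$mouse_id)
  bouts <- lapply(stats::setNames(mice, mice), mouse_bouts, log = log,
                  min_trials = min_trials, window_s = bout_window_s,
                  sr_first_n = sr_first_n)
  rows <- list()
  for (m in mice) {
    b <- bouts[[m]]
    if (nrow(b) < 2) next
    for (i in seq_len(nrow(b) - 1L)) {
      gap <- b$t_start[i + 1L] - b$t_end[i]
      if (gap < gap_min_s || gap > gap_max_s) next
      # disqualified if any peer bout overlaps the gap interval
      peer_hit <- FALSE
      for (p in setdiff(mice, m)) {
        pb <- bouts[[p]]
        if (nrow(pb) && any(pb$t_start < b$t_start[i + 1L] &
                              pb$t_end > b$t_end[i])) {
          peer_hit <- TRUE
          break
        }
      }
      if (peer_hit) next
      sr1 <- b$sr[i]; sr2 <- b$sr[i + 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = m,
        t_b1_start = b$t_start[i], t_b1_end = b$t_end[i],
        t_b2_start = b$t_start[i + 1L], t_b2_end = b$t_end[i + 1L],
        n_b1 = b$n[i], n_b2 = b$n[i + 1L],
        sr_bout1 = sr1, sr_bout2 = sr2,
        delta_success = if (sr1 > 0) (sr2 - sr1) / sr1 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(mouse_id = character(), t_b1_start = numeric(),
                      t_b1_end = numeric(), t_b2_start = numeric(),
                      t_b2_end = numeric(), n_b1 = integer(),
                      n_b2 = integer(), sr_bout1 = numeric(),
                      sr_bout2 = numeric(), delta_success = numeric()))
  }
  do.call(rbind, rows)
}

#' Summarise peer-influence effects
#'
#' Group means and standard errors of the relative success-rate change,
#' by follower genotype and influencer class, alongside the solitary
#' controls. Events with a zero baseline success rate (undefined relative
#' change) are excluded from the means and counted separately.
#'
#' @param motifs Output of [find_motifs()].
#' @param controls Output of [find_controls()].
#' @param genotypes Named character vector, mouse id to genotype label.
#' @return Data frame with columns `genotype`, `condition`
#'   (`good_influencer`, `bad_influencer`, `control`), `n`, `n_zero_baseline`,
#'   `mean_delta`, `sem_delta`.
#' @export
influence_summary <- function(motifs, controls, genotypes) {
  grp <- function(ids, deltas, condition) {
    g <- unname(genotypes[ids])
    out <- lapply(unique(g[!is.na(g)]), function(gen) {
      d <- deltas[!is.na(g) & g == gen]
      nz <- sum(is.na(d))
      d <- d[!is.na(d)]
      data.frame(genotype = gen, condition = condition,
                 n = length(d), n_zero_baseline = nz,
                 mean_delta = if (length(d)) mean(d) else NA_real_,
                 sem_delta = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  res <- list()
  if (nrow(motifs)) {
    for (cl in c("good", "bad")) {
      sel <- motifs$influencer_class == cl
      if (any(sel)) {
        res[[length(res) + 1L]] <- grp(motifs$follower_id[sel],
                                       motifs$delta_success[sel],
                                       paste0(cl, "_influencer"))
      }
    }
  }
  if (nrow(controls)) {
    res[[length(res) + 1L]] <- grp(controls$mouse_id,
                                   controls$delta_success, "control")
  }
  if (!length(res)) {
    return(data.frame(genotype = character(), condition = character(),
                      n = integer(), n_zero_baseline = integer(),
                      mean_delta = numeric(), sem_delta = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
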