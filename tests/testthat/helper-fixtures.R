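# Fixture builders shared across test files. All logs are generated in code.

# A hand-built session log from a bout specification. Each bout is a list
# with: mouse, t0 (first trial time), n (trials), n_succ (successes, placed
# first), spacing (s between trials, default 20). Stage-2 trials with
# required 0.5 s; successes hold 0.6 s, failures 0.1 s.
make_bout_log <- function(bouts, genotypes = NULL) {
  trials <- list()
  entries <- list()
  tid <- 0L
  for (i in seq_along(bouts)) {
    b <- bouts[[i]]
    spacing <- b$spacing %||% 20
    tt <- b$t0 + (seq_len(b$n) - 1) * spacing
    succ <- c(rep(TRUE, b$n_succ), rep(FALSE, b$n - b$n_succ))
    ids <- sprintf("T%04d", tid + seq_len(b$n))
    tid <- tid + b$n
    eid <- sprintf("E%03d", i)
    trials[[i]] <- data.frame(
      trial_id = ids, mouse_id = b$mouse, entry_id = eid, t_start = tt,
      stage = 2L, required_hold_time = 0.5,
      hold_time = ifelse(succ, 0.6, 0.1), success = succ,
      trajectory_ref = NA_character_, stringsAsFactors = FALSE)
    entries[[i]] <- data.frame(entry_id = eid, mouse_id = b$mouse,
                               t_enter = b$t0 - 1,
                               t_exit = tt[b$n] + 1,
                               stringsAsFactors = FALSE)
  }
  trials <- do.call(rbind, trials)
  entries <- do.call(rbind, entries)
  mice <- unique(trials$mouse_id)
  if (is.null(genotypes)) {
    genotypes <- stats::setNames(rep("WT", length(mice)), mice)
  }
  session_log(trials, entries,
              metadata = list(cage_id = "fixture", day0 = "2024-01-01",
                              genotypes = genotypes))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-agent simulated cage reused by several tests (no trajectories).
fast_sim <- function(seed = 1, n_days = 4, trajectories = FALSE, ...) {
  cfg <- sim_config(list(wt_agent(), hd_agent()), n_days = n_days,
                    seed = seed, trajectories = trajectories, ...)
  simulate_cage(cfg)
}

# Mixture sampler used as generator for recovery tests (untruncated
# Gaussian component, matching the fitting model).
rmix <- function(n, w, kappa = 5, mu = 0.55, sigma = 0.1) {
  u <- runif(n) < w
  x <- numeric(n)
  x[u] <- rexp(sum(u), kappa)
  x[!u] <- rnorm(sum(!u), mu, sigma)
  pmax(x, 0)
}

# Independent exhaustive-path DTW oracle: enumerates every monotone warping
# path through the n x m lattice and takes the cheapest. Exponential in the
# input sizes; only usable for tiny sequences, which is the point.
dtw_oracle <- function(a, b) {
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + abs(a[i] - b[j])
    if (acc >= best) return()
    if (i == n && j == m) {
      best <<- acc
      return()
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
  }
  walk(1, 1, 0)
  best
}

# All sequences of length 1..len over the given alphabet.
all_seqs <- function(len, alphabet = 0:2) {
  out <- list()
  for (l in seq_len(len)) {
    g <- do.call(expand.grid, rep(list(alphabet), l))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) as.numeric(g[i, ])))
  }
  out
}
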