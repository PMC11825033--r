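test_that("DTW matches hand-checked values and basic identities", {
  expect_equal(dtw_distance(c(0, 1, 2), c(0, 2)), 1)
  expect_equal(dtw_distance(1:5, 1:5), 0)
  expect_error(dtw_distance(numeric(), 1:3), "empty")
  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    expect_equal(dtw_distance(a, b), dtw_distance(b, a))
    expect_equal(dtw_distance(a, a), 0)
  }
})

test_that("DTW agrees with the exhaustive-path oracle on random pairs", {
  set.seed(2)
  for (i in 1:30) {
    a <- sample(0:3, sample(1:5, 1), replace = TRUE)
    b <- sample(0:3, sample(1:5, 1), replace = TRUE)
    expect_equal(dtw_distance(a, b), dtw_oracle(a, b))
  }
})

test_that("moving SD uses centred shrunk windows and z-scores to mean 0/SD 1", {
  ms <- moving_std_holdtimes(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(ms$raw[3], sd(c(0.1, 0.2, 0.3, 0.4, 0.5)))
  expect_equal(ms$raw[1], sd(c(0.1, 0.2, 0.3)))  # shrunk edge window
  expect_equal(mean(ms$z), 0, tolerance = 1e-9)
  expect_equal(sd(ms$z), 1, tolerance = 1e-9)
  # locality: values far outside a window do not affect it
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- c(1, 2, 3, 4, 5, 6, 7, 9, 8)
  expect_equal(moving_std_holdtimes(x)$raw[3], moving_std_holdtimes(y)$raw[3])
  # constant input is degenerate
  msc <- moving_std_holdtimes(rep(0.3, 10))
  expect_true(all(msc$raw == 0))
  expect_true(attr(msc, "degenerate"))
})

test_that("consecutive DTW z-scores within mouse and flags degenerate spread", {
  log <- simulate_cage(sim_config(list(wt_agent("A")), n_days = 1, seed = 4))
  cd <- consecutive_dtw(log, "A")
  expect_gt(nrow(cd), 10)
  expect_equal(mean(cd$z), 0, tolerance = 1e-9)
  expect_equal(sd(cd$z), 1, tolerance = 1e-9)
  expect_false(attr(cd, "degenerate"))
  # identical trajectories -> zero distances -> degenerate
  tra <- synth_trajectory(0.3, 0, plateau = 15, trial_id = "T1")
  trials <- data.frame(trial_id = sprintf("T%d", 1:3), mouse_id = "m",
                       entry_id = "E1", t_start = c(10, 40, 70), stage = 2L,
                       required_hold_time = 0.2, hold_time = 0.3,
                       success = TRUE, trajectory_ref = "T1")
  entries <- data.frame(entry_id = "E1", mouse_id = "m", t_enter = 5,
                        t_exit = 90)
  lg <- session_log(trials, entries, list(T1 = tra),
                    metadata = list(genotypes = c(m = "WT")))
  cdd <- consecutive_dtw(lg, "m")
  expect_true(attr(cdd, "degenerate"))
  expect_true(all(cdd$dtw == 0))
  # fewer than two trials -> empty
  expect_equal(nrow(consecutive_dtw(lg, "nobody")), 0L)
})

test_that("window bouts follow the greedy 10-in-300s rule", {
  # 9 trials in 5 minutes is not a bout
  expect_equal(nrow(find_window_bouts(seq(0, by = 30, length.out = 9))), 0L)
  # 10 trials spanning exactly 300 s qualifies
  b <- find_window_bouts(seq(0, 300, length.out = 10))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end), c(1L, 10L))
  # a bout extends while the trailing 10-trial span stays inside the window
  t2 <- c(seq(0, by = 10, length.out = 15), 5000)
  b2 <- find_window_bouts(t2)
  expect_equal(c(b2$start, b2$end), c(1L, 15L))
  # two separated clusters give two bouts
  t3 <- c(seq(0, by = 10, length.out = 10), seq(10000, by = 10, length.out = 12))
  expect_equal(nrow(find_window_bouts(t3)), 2L)
})

test_that("hold-time-change alignment extracts 5-before/15-after windows", {
  log <- fast_sim(seed = 31, n_days = 5, trajectories = TRUE)
  al <- align_to_holdtime_change(log, "WT1", max_day = 5)
  expect_gt(nrow(al), 0)
  ev1 <- al[al$event_id == al$event_id[1], ]
  expect_equal(nrow(ev1), 20L)  # 5 before + 15 after
  expect_equal(ev1$position, c(-5:-1, 1:15))
  # success drops right after the requirement increase
  post <- al$success[al$position >= 1 & al$position <= 5]
  pre <- al$success[al$position <= -1]
  expect_lt(mean(post), mean(pre))
  # a mouse with no requirement change yields an empty result
  log0 <- fast_sim(seed = 32, n_days = 2)
  al0 <- align_to_holdtime_change(log0, "HD1", max_day = 1)
  expect_equal(nrow(al0), 0L)
})

test_that("bout variability averages consecutive-DTW z by bout position", {
  log <- simulate_cage(sim_config(list(wt_agent("A", entry_rate = 3,
                                                 bout_geom_p = 0.06)),
                                  n_days = 2, seed = 33))
  bv <- bout_variability(log, "A", max_day = 2)
  expect_equal(bv$position, 1:10)
  expect_gt(max(bv$n_bouts), 0)
  long <- attr(bv, "per_bout")
  expect_equal(mean(long$dtw_z, na.rm = TRUE), 0, tolerance = 1e-9)
  # 10 identical trials give a degenerate z-series
  tra <- synth_trajectory(0.3, 0, plateau = 15, trial_id = "T1")
  trials <- data.frame(trial_id = sprintf("T%02d", 1:11), mouse_id = "m",
                       entry_id = "E1", t_start = seq(10, by = 20,
                                                      length.out = 11),
                       stage = 2L, required_hold_time = 0.2, hold_time = 0.3,
                       success = TRUE, trajectory_ref = "T1")
  entries <- data.frame(entry_id = "E1", mouse_id = "m", t_enter = 5,
                        t_exit = 240)
  lg <- session_log(trials, entries, list(T1 = tra),
                    metadata = list(genotypes = c(m = "WT")))
  bvd <- bout_variability(lg, "m", max_day = 2)
  expect_true(attr(bvd, "degenerate"))
})

test_that("outcome runs respect the 5-trial/150-s criterion", {
  mk_run_log <- function(times, successes) {
    n <- length(times)
    tra <- lapply(seq_len(n), function(i) {
      synth_trajectory(0.1 + 0.01 * i, 0, plateau = 12,
                       trial_id = sprintf("T%02d", i))
    })
    names(tra) <- sprintf("T%02d", seq_len(n))
    trials <- data.frame(trial_id = names(tra), mouse_id = "m",
                         entry_id = "E1", t_start = times, stage = 2L,
                         required_hold_time = 0.5,
                         hold_time = ifelse(successes, 0.6, 0.1),
                         success = successes, trajectory_ref = names(tra))
    entries <- data.frame(entry_id = "E1", mouse_id = "m",
                          t_enter = times[1] - 1, t_exit = times[n] + 1)
    session_log(trials, entries, tra,
                metadata = list(genotypes = c(m = "WT")))
  }
  # 5 successes spanning 150 s: one run, 4 pair positions
  lg <- mk_run_log(seq(0, 150, length.out = 5) + 10, rep(TRUE, 5))
  rv <- outcome_run_variability(lg, "m", "success")
  expect_equal(rv$position, 1:4)
  expect_equal(max(rv$n_runs), 1L)
  # spanning 151 s: excluded
  lg2 <- mk_run_log(seq(0, 151, length.out = 5) + 10, rep(TRUE, 5))
  rv2 <- outcome_run_variability(lg2, "m", "success")
  expect_equal(max(rv2$n_runs), 0L)
  # alternating outcomes: no runs
  lg3 <- mk_run_log(seq(10, by = 20, length.out = 8),
                    rep(c(TRUE, FALSE), 4))
  expect_equal(max(outcome_run_variability(lg3, "m", "success")$n_runs), 0L)
  # a 7-long run contributes only its first 5-trial window
  lg4 <- mk_run_log(seq(10, by = 10, length.out = 7), rep(TRUE, 7))
  rv4 <- outcome_run_variability(lg4, "m", "success")
  expect_equal(max(rv4$n_runs), 1L)
})
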