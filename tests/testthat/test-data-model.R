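test_that("save/load round trip reproduces a simulated log exactly", {
  log <- simulate_cage(sim_config(list(wt_agent(), hd_agent()), n_days = 1,
                                  seed = 1, trajectories = TRUE))
  d <- withr::local_tempdir()
  save_session(log, d)
  log2 <- load_session(d)
  expect_equal(log2$trials, log$trials)
  expect_equal(log2$entries, log$entries)
  expect_setequal(names(log2$trajectories), names(log$trajectories))
  id <- names(log$trajectories)[[1]]
  expect_identical(log2$trajectories[[id]]$angle, log$trajectories[[id]]$angle)
  expect_equal(log2$metadata$genotypes, log$metadata$genotypes)
})

test_that("saving is byte-deterministic", {
  log <- simulate_cage(sim_config(list(wt_agent()), n_days = 1, seed = 7,
                                  trajectories = FALSE))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  save_session(log, d1)
  save_session(load_session(d1), d2)
  for (f in c("trials.csv", "entries.csv", "metadata.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("an empty log saves to header-only tables and loads back", {
  log <- session_log(data.frame(), data.frame(),
                     metadata = list(cage_id = "c", day0 = "2024-01-01",
                                     genotypes = character()))
  d <- withr::local_tempdir()
  save_session(log, d)
  expect_equal(length(readLines(file.path(d, "trials.csv"))), 1L)
  log2 <- load_session(d)
  expect_equal(nrow(log2$trials), 0L)
  expect_equal(nrow(log2$entries), 0L)
})

test_that("a trajectory saves one row per sample", {
  tr <- trajectory("T1", rep(10, 400))
  trials <- data.frame(trial_id = "T1", mouse_id = "m", entry_id = "E1",
                       t_start = 10, stage = 2L, required_hold_time = 0.5,
                       hold_time = 1, success = TRUE, trajectory_ref = "T1")
  entries <- data.frame(entry_id = "E1", mouse_id = "m", t_enter = 5,
                        t_exit = 20)
  log <- session_log(trials, entries, list(T1 = tr),
                     metadata = list(genotypes = c(m = "WT")))
  d <- withr::local_tempdir()
  save_session(log, d)
  expect_equal(length(readLines(file.path(d, "trajectories", "T1.csv"))),
               401L)
})

test_that("loading names missing files and unknown entry ids", {
  d <- withr::local_tempdir()
  expect_error(load_session(d), "trials.csv")
  log <- simulate_cage(sim_config(list(wt_agent()), n_days = 1, seed = 2,
                                  trajectories = FALSE))
  save_session(log, d)
  tr <- read.csv(file.path(d, "trials.csv"))
  tr$entry_id[1] <- "E99"
  write.csv(tr, file.path(d, "trials.csv"), row.names = FALSE)
  expect_error(load_session(d), "E99")
})

test_that("validation rejects each broken invariant", {
  base_tr <- data.frame(trial_id = c("T1", "T2"), mouse_id = "m",
                        entry_id = "E1", t_start = c(10, 20), stage = 2L,
                        required_hold_time = 0.5,
                        hold_time = c(0.6, 0.1), success = c(TRUE, FALSE),
                        trajectory_ref = NA_character_)
  base_en <- data.frame(entry_id = "E1", mouse_id = "m", t_enter = 5,
                        t_exit = 50)
  md <- list(genotypes = c(m = "WT"))
  expect_silent(validate_session_log(
    session_log(base_tr, base_en, metadata = md, validate = FALSE)))
  # wrong success flag
  bad <- base_tr; bad$success[2] <- TRUE
  expect_error(session_log(bad, base_en, metadata = md), "success")
  # negative hold time
  bad <- base_tr; bad$hold_time[1] <- -0.1
  expect_error(session_log(bad, base_en, metadata = md), "hold_time")
  # requirement above the cap
  bad <- base_tr; bad$required_hold_time <- 1.5; bad$hold_time <- c(1.6, 0.1)
  expect_error(session_log(bad, base_en, metadata = md), "required")
  # duplicate trial times for one mouse
  bad <- base_tr; bad$t_start <- c(10, 10)
  expect_error(session_log(bad, base_en, metadata = md), "increasing")
  # overlapping entries
  en2 <- rbind(base_en, data.frame(entry_id = "E2", mouse_id = "m",
                                   t_enter = 40, t_exit = 60))
  tr2 <- base_tr
  expect_error(session_log(tr2, en2, metadata = md), "overlapping")
  # dangling trajectory reference
  bad <- base_tr; bad$trajectory_ref <- c("TX", NA)
  expect_error(session_log(bad, base_en, metadata = md), "TX")
  # mouse absent from the genotype map
  expect_error(session_log(base_tr, base_en,
                           metadata = list(genotypes = c(other = "WT"))),
               "genotype")
})

test_that("round-trip identity holds across random small logs", {
  for (seed in 1:4) {
    log <- simulate_cage(sim_config(list(wt_agent(), hd_agent()),
                                    n_days = 1, seed = seed,
                                    trajectories = FALSE))
    d <- withr::local_tempdir()
    save_session(log, d)
    log2 <- load_session(d)
    expect_equal(log2$trials, log$trials, info = paste("seed", seed))
    expect_equal(log2$entries, log$entries, info = paste("seed", seed))
  }
})

test_that("day indexing is 1-based from the session epoch", {
  expect_equal(day_of(c(0, 86399, 86400, 200000)), c(1L, 1L, 2L, 3L))
})
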