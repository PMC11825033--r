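test_that("a textbook follower-influencer-follower timeline yields one motif", {
  log <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 200 / 9),
    list(mouse = "B", t0 = 300, n = 10, n_succ = 8, spacing = 200 / 9),
    list(mouse = "A", t0 = 600, n = 10, n_succ = 6, spacing = 200 / 9)))
  m <- find_motifs(log)
  expect_equal(nrow(m), 1L)
  expect_equal(m$follower_id, "A")
  expect_equal(m$influencer_id, "B")
  expect_equal(m$influencer_class, "good")
  expect_equal(m$delta_success, (0.6 - 0.4) / 0.4)
})

test_that("influencer class flips when the middle bout underperforms", {
  log <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 200 / 9),
    list(mouse = "B", t0 = 300, n = 10, n_succ = 3, spacing = 200 / 9),
    list(mouse = "A", t0 = 600, n = 10, n_succ = 6, spacing = 200 / 9)))
  m <- find_motifs(log)
  expect_equal(m$influencer_class, "bad")
  # equal success is also "bad" (same-or-lower rule)
  log2 <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 200 / 9),
    list(mouse = "B", t0 = 300, n = 10, n_succ = 4, spacing = 200 / 9),
    list(mouse = "A", t0 = 600, n = 10, n_succ = 6, spacing = 200 / 9)))
  expect_equal(find_motifs(log2)$influencer_class, "bad")
})

test_that("motif gaps respect the 300 s boundary exactly", {
  mk <- function(gap) make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 5, spacing = 200 / 9),
    list(mouse = "B", t0 = 200 + gap, n = 10, n_succ = 8, spacing = 200 / 9),
    list(mouse = "A", t0 = 200 + gap + 200 + 100, n = 10, n_succ = 6,
         spacing = 200 / 9)))
  expect_equal(nrow(find_motifs(mk(299))), 1L)
  expect_equal(nrow(find_motifs(mk(300))), 1L)
  expect_equal(nrow(find_motifs(mk(301))), 0L)
})

test_that("bouts below 10 trials never anchor a motif", {
  log <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 9, n_succ = 4, spacing = 20),
    list(mouse = "B", t0 = 300, n = 10, n_succ = 8, spacing = 20),
    list(mouse = "A", t0 = 700, n = 10, n_succ = 6, spacing = 20)))
  expect_equal(nrow(find_motifs(log)), 0L)
  # 11-trial bouts qualify
  log2 <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 11, n_succ = 4, spacing = 20),
    list(mouse = "B", t0 = 450, n = 11, n_succ = 8, spacing = 20),
    list(mouse = "A", t0 = 900, n = 11, n_succ = 6, spacing = 20)))
  expect_equal(nrow(find_motifs(log2)), 1L)
})

test_that("single-mouse logs yield no motifs", {
  log <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 20),
    list(mouse = "A", t0 = 600, n = 10, n_succ = 6, spacing = 20)))
  expect_equal(nrow(find_motifs(log)), 0L)
})

test_that("motif detection is invariant to relabeling mice", {
  bouts <- list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 20),
    list(mouse = "B", t0 = 400, n = 10, n_succ = 8, spacing = 20),
    list(mouse = "A", t0 = 800, n = 10, n_succ = 6, spacing = 20),
    list(mouse = "B", t0 = 1300, n = 12, n_succ = 6, spacing = 20),
    list(mouse = "A", t0 = 1800, n = 10, n_succ = 2, spacing = 20))
  m1 <- find_motifs(make_bout_log(bouts))
  swap <- lapply(bouts, function(b) {
    b$mouse <- if (b$mouse == "A") "B" else "A"
    b
  })
  m2 <- find_motifs(make_bout_log(swap))
  expect_equal(nrow(m1), nrow(m2))
  expect_equal(sort(m1$delta_success), sort(m2$delta_success))
  expect_equal(m1$follower_id, chartr("AB", "BA", m2$follower_id))
})

test_that("reported motifs satisfy their own invariants when re-checked", {
  log <- simulate_cage(sim_config(
    list(wt_agent("A", entry_rate = 8, bout_geom_p = 0.07),
         wt_agent("B", entry_rate = 8, bout_geom_p = 0.07)),
    n_days = 3, seed = 41, trajectories = FALSE,
    start_stage = 2, start_required = 0.3))
  m <- find_motifs(log)
  expect_gt(nrow(m), 0)
  expect_true(all(m$n_b1 >= 10 & m$n_b2 >= 10 & m$n_b3 >= 10))
  expect_true(all(m$t_b2_start - m$t_b1_end <= 300))
  expect_true(all(m$t_b3_start - m$t_b2_end <= 300))
  expect_true(all(m$t_b1_end < m$t_b2_start | m$t_b1_end <= m$t_b2_start))
  expect_true(all(m$follower_id != m$influencer_id))
  ok_delta <- !is.na(m$delta_success)
  expect_equal(m$delta_success[ok_delta],
               ((m$sr_after - m$sr_baseline) / m$sr_baseline)[ok_delta])
  expect_equal(unique(m$influencer_class[m$sr_influencer > m$sr_baseline]),
               "good")
})

test_that("solitary controls require a 5-15 min quiet gap", {
  # 10 minutes apart: one control
  log <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 20),
    list(mouse = "A", t0 = 200 + 600, n = 10, n_succ = 6, spacing = 20)))
  ct <- find_controls(log)
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$delta_success, 0.5)
  # 4 minutes: below the floor
  log2 <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 20),
    list(mouse = "A", t0 = 200 + 240, n = 10, n_succ = 6, spacing = 20)))
  expect_equal(nrow(find_controls(log2)), 0L)
  # 16 minutes: above the ceiling
  log3 <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 20),
    list(mouse = "A", t0 = 200 + 960, n = 10, n_succ = 6, spacing = 20)))
  expect_equal(nrow(find_controls(log3)), 0L)
  # an intervening peer bout disqualifies the pair
  log4 <- make_bout_log(list(
    list(mouse = "A", t0 = 0, n = 10, n_succ = 4, spacing = 20),
    list(mouse = "B", t0 = 300, n = 10, n_succ = 5, spacing = 20),
    list(mouse = "A", t0 = 200 + 600, n = 10, n_succ = 6, spacing = 20)))
  expect_equal(nrow(find_controls(log4)), 0L)
})

test_that("influence summary groups deltas and guards zero baselines", {
  motifs <- data.frame(
    follower_id = c("A", "A", "B"), influencer_id = c("B", "B", "A"),
    influencer_class = c("good", "good", "bad"),
    delta_success = c(0.5, 0.3, NA), sr_baseline = c(0.4, 0.5, 0),
    stringsAsFactors = FALSE)
  controls <- data.frame(mouse_id = c("A", "B"),
                         delta_success = c(0, 0.1),
                         stringsAsFactors = FALSE)
  s <- influence_summary(motifs, controls, c(A = "WT", B = "HD"))
  good_wt <- s[s$condition == "good_influencer" & s$genotype == "WT", ]
  expect_equal(good_wt$mean_delta, 0.4)
  expect_equal(good_wt$n, 2L)
  bad_hd <- s[s$condition == "bad_influencer" & s$genotype == "HD", ]
  expect_equal(bad_hd$n, 0L)
  expect_equal(bad_hd$n_zero_baseline, 1L)
  expect_equal(s$mean_delta[s$condition == "control" & s$genotype == "WT"], 0)
})
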