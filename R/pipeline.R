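#' Pipeline configuration
#'
#' Parameters for the full analysis battery, defaulting to the study's
#' stated analysis conventions: daily metrics standardized to the first 58
#' days, mixture fits on days with at least 30 usable trials, 10-trials-in-
#' 5-minutes window bouts, 5-trial/150 s outcome runs, motif gaps of at most
#' 5 minutes and control gaps of 5--15 minutes.
#'
#' @param replication_mode Standardize daily metrics to the first 58 days
#'   (default `TRUE`; `FALSE` uses each mouse's full duration).
#' @param n_days Length of the standardized window (default 58).
#' @param min_fit_trials Minimum trials for a daily mixture fit.
#' @param bout_min_trials,bout_window_s Window-bout criterion.
#' @param run_len,run_span_s Outcome-run criterion.
#' @param motif_max_gap_s,control_gap_min_s,control_gap_max_s Social motif
#'   and control gap limits.
#' @param bout_size_cap Top bin of the entry-bout-size histogram.
#' @param seed Seed recorded in the manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(replication_mode = TRUE, n_days = 58,
                            min_fit_trials = 30, bout_min_trials = 10,
                            bout_window_s = 300, run_len = 5,
                            run_span_s = 150, motif_max_gap_s = 300,
                            control_gap_min_s = 300, control_gap_max_s = 900,
                            bout_size_cap = 14, seed = 1) {
  structure(list(replication_mode = replication_mode, n_days = n_days,
                 min_fit_trials = min_fit_trials,
                 bout_min_trials = bout_min_trials,
                 bout_window_s = bout_window_s, run_len = run_len,
                 run_span_s = run_span_s, motif_max_gap_s = motif_max_gap_s,
                 control_gap_min_s = control_gap_min_s,
                 control_gap_max_s = control_gap_max_s,
                 bout_size_cap = bout_size_cap, seed = seed),
            class = "pipeline_config")
}

fmt9 <- function(x) {
  if (is.numeric(x)) {
    out <- sprintf("%.9g", x)
    out[is.na(x)] <- ""
    out
  } else if (is.logical(x)) {
    as.character(as.integer(x))
  } else as.character(x)
}

write_result_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt9), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
}

log_digest <- function(log) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  tr <- log$trials
  writeLines(c(paste(fmt17(tr$t_start), collapse = ","),
               paste(fmt17(tr$hold_time), collapse = ","),
               paste(tr$mouse_id, collapse = ",")), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis battery on a session log
#'
#' Executes engagement, entry-bout, daily mixture-fit, jerkiness,
#' variability (hold-time-change alignment, window bouts, outcome runs) and
#' social-influence analyses for every mouse, and writes one CSV per
#' analysis plus a JSON manifest (package version, seed, configuration,
#' input digest) into `out_dir`. Output numbers are written with 9
#' significant digits and fixed column orders, so re-running on the same
#' input reproduces byte-identical files.
#'
#' @param log A [session_log()] or a path to a directory readable by
#'   [load_session()].
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the result data frames (also on disk:
#'   `engagement.csv`, `bouts.csv`, `mixture_fits.csv`, `jerkiness.csv`,
#'   `variability.csv`, `social.csv`, `manifest.json`).
#' @export
run_pipeline <- function(log, out_dir, config = pipeline_config()) {
  if (is.character(log)) log <- load_session(log)
  validate_session_log(log)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mice <- sort(unique(log$trials$mouse_id))
  max_day <- if (config$replication_mode) config$n_days else NULL
  days <- seq_len(if (is.null(max_day)) {
    if (nrow(log$trials)) max(day_of(log$trials$t_start)) else 1L
  } else max_day)

  engagement <- do.call(rbind, lapply(mice, daily_engagement, log = log,
                                      days = days))
  bouts <- do.call(rbind, lapply(mice, function(m) {
    b <- entry_bout_sizes(log, m, size_cap = config$bout_size_cap)
    cbind(mouse_id = m, b)
  }))
  fits <- do.call(rbind, lapply(mice, function(m) {
    f <- w_trajectory(log, m, days = days,
                      min_fit_trials = config$min_fit_trials)
    cbind(mouse_id = m, f)
  }))
  jerk <- do.call(rbind, lapply(mice, function(m) {
    cbind(mouse_id = m, daily_jerkiness(log, m, days = days))
  }))
  variability <- do.call(rbind, lapply(mice, function(m) {
    ev <- align_to_holdtime_change(log, m, max_day = max_day)
    ev_part <- if (nrow(ev)) {
      data.frame(mouse_id = m, analysis = "holdtime_change",
                 unit = ev$event_id, position = ev$position,
                 success = ev$success, dtw_z = ev$dtw_z,
                 movstd_z = ev$movstd_z, stringsAsFactors = FALSE)
    }
    bv <- bout_variability(log, m, min_trials = config$bout_min_trials,
                           window_s = config$bout_window_s,
                           max_day = max_day)
    bv_part <- data.frame(mouse_id = m, analysis = "window_bout",
                          unit = sprintf("n_bouts=%d", bv$n_bouts),
                          position = bv$position, success = NA_integer_,
                          dtw_z = bv$mean_dtw_z, movstd_z = NA_real_,
                          stringsAsFactors = FALSE)
    runs <- do.call(rbind, lapply(c("success", "failure"), function(oc) {
      rv <- outcome_run_variability(log, m, outcome = oc,
                                    run_len = config$run_len,
                                    span_s = config$run_span_s,
                                    max_day = max_day)
      data.frame(mouse_id = m, analysis = paste0(oc, "_runs"),
                 unit = sprintf("n_runs=%d", rv$n_runs),
                 position = rv$position, success = NA_integer_,
                 dtw_z = rv$mean_dtw_z, movstd_z = NA_real_,
                 stringsAsFactors = FALSE)
    }))
    rbind(ev_part, bv_part, runs)
  }))
  motifs <- find_motifs(log, min_trials = config$bout_min_trials,
                        bout_window_s = config$bout_window_s,
                        max_gap_s = config$motif_max_gap_s)
  controls <- find_controls(log, min_trials = config$bout_min_trials,
                            bout_window_s = config$bout_window_s,
                            gap_min_s = config$control_gap_min_s,
                            gap_max_s = config$control_gap_max_s)
  geno <- log$metadata$genotypes
  summ <- influence_summary(motifs, controls, geno)
  social <- rbind(
    if (nrow(motifs)) data.frame(event_type = "motif",
                                 mouse_id = motifs$follower_id,
                                 partner_id = motifs$influencer_id,
                                 t_start = motifs$t_b1_start,
                                 influencer_class = motifs$influencer_class,
                                 sr_baseline = motifs$sr_baseline,
                                 sr_middle = motifs$sr_influencer,
                                 sr_after = motifs$sr_after,
                                 delta_success = motifs$delta_success,
                                 stringsAsFactors = FALSE),
    if (nrow(controls)) data.frame(event_type = "control",
                                   mouse_id = controls$mouse_id,
                                   partner_id = NA_character_,
                                   t_start = controls$t_b1_start,
                                   influencer_class = NA_character_,
                                   sr_baseline = controls$sr_bout1,
                                   sr_middle = NA_real_,
                                   sr_after = controls$sr_bout2,
                                   delta_success = controls$delta_success,
                                   stringsAsFactors = FALSE))
  if (is.null(social)) {
    social <- data.frame(event_type = character(), mouse_id = character(),
                         partner_id = character(), t_start = numeric(),
                         influencer_class = character(),
                         sr_baseline = numeric(), sr_middle = numeric(),
                         sr_after = numeric(), delta_success = numeric())
  }

  results <- list(engagement = engagement, bouts = bouts,
                  mixture_fits = fits, jerkiness = jerk,
                  variability = variability, social = social)
  for (nm in names(results)) {
    write_result_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  manifest <- list(
    package = "leverlog",
    version = as.character(utils::packageVersion("leverlog")),
    seed = config$seed,
    config = unclass(config)[order(names(unclass(config)))],
    input_digest = log_digest(log),
    n_trials = nrow(log$trials), n_mice = length(mice))
  writeLines(manifest_json(manifest), file.path(out_dir, "manifest.json"))
  results$influence_summary <- summ
  invisible(results)
}

# minimal deterministic JSON writer (scalars, lists, vectors)
manifest_json <- function(x, indent = 0) {
  pad <- strrep("  ", indent)
  if (is.list(x)) {
    items <- vapply(seq_along(x), function(i) {
      paste0(pad, "  \"", names(x)[i], "\": ",
             sub("^\\s+", "", manifest_json(x[[i]], indent + 1)))
    }, character(1))
    paste0(pad, "{\n", paste(items, collapse = ",\n"), "\n", pad, "}")
  } else if (length(x) == 1) {
    if (is.character(x)) paste0(pad, "\"", x, "\"")
    else if (is.logical(x)) paste0(pad, tolower(as.character(x)))
    else paste0(pad, fmt9(x))
  } else {
    paste0(pad, "[", paste(vapply(x, function(v) {
      sub("^\\s+", "", manifest_json(v, 0))
    }, character(1)), collapse = ", "), "]")
  }
}

#' End-to-end demonstration: simulate a cage and analyse it
#'
#' Simulates a two-agent cage (one wild-type-like learner, one
#' Huntington-model-like non-learner) for `n_days` days in closed loop with
#' the adaptive scheduler, then runs the full analysis battery on the
#' simulated log.
#'
#' @param seed Integer seed for the simulation.
#' @param out_dir Output directory for the pipeline CSVs.
#' @param n_days Days to simulate (default 58).
#' @param trajectories Synthesize trajectories (default `TRUE`).
#' @return Invisibly, a list with the simulated `log`, the pipeline
#'   `results`, and the `scheduler_trace`.
#' @export
run_demo <- function(seed = 11, out_dir = tempfile("leverlog_demo"),
                     n_days = 58, trajectories = TRUE) {
  cfg <- sim_config(list(wt_agent(), hd_agent()), n_days = n_days,
                    seed = seed, trajectories = trajectories)
  log <- simulate_cage(cfg)
  res <- run_pipeline(log, out_dir,
                      config = pipeline_config(n_days = n_days, seed = seed))
  invisible(list(log = log, results = res,
                 scheduler_trace = attr(log, "scheduler_trace"),
                 out_dir = out_dir))
}
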