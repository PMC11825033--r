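#' Lever trajectory for a single trial
#'
#' A lever-angle time series sampled at a fixed 400 Hz, in degrees within the
#' physical movement range 0--30.
#'
#' @param trial_id Character scalar identifying the trial.
#' @param angle Numeric vector of lever angles in degrees, each in `[0, 30]`.
#' @param fs Sampling rate in Hz; the hardware samples at 400 Hz.
#' @return An object of class `"trajectory"`: a list with elements `trial_id`,
#'   `fs` and `angle`.
#' @examples
#' tr <- trajectory("T1", c(0, 2, 7, 15, 15, 8, 1))
#' length(tr$angle)
#' @export
trajectory <- function(trial_id, angle, fs = 400) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L)
  angle <- as.numeric(angle)
  if (length(angle) < 1L) {
    stop("trajectory '", trial_id, "': angle must have length >= 1")
  }
  if (fs != 400) {
    stop("trajectory '", trial_id, "': fs must be 400 Hz")
  }
  if (anyNA(angle) || any(angle < 0) || any(angle > 30)) {
    stop("trajectory '", trial_id, "': angles must lie within [0, 30] degrees")
  }
  structure(list(trial_id = trial_id, fs = fs, angle = angle),
            class = "trajectory")
}

#' Session log: the multi-animal home-cage event record
#'
#' Bundles per-trial records, chamber entry/exit records, per-trial lever
#' trajectories and cage metadata into one validated object. Timestamps are
#' seconds since the session epoch (midnight of `day0`), so calendar day
#' `d` spans `[(d-1)*86400, d*86400)`.
#'
#' @param trials Data frame with columns `trial_id`, `mouse_id`, `entry_id`,
#'   `t_start` (s), `stage` (1 or 2), `required_hold_time` (s, in `[0, 1]`),
#'   `hold_time` (s, `>= 0`), `success` (logical), and optionally
#'   `trajectory_ref` (character or `NA`).
#' @param entries Data frame with columns `entry_id`, `mouse_id`, `t_enter`,
#'   `t_exit` (seconds).
#' @param trajectories Named list of [trajectory()] objects keyed by trial id.
#' @param metadata List with `cage_id`, `day0` (date string) and `genotypes`
#'   (named character vector, mouse id to `"WT"` or `"HD"`).
#' @param validate Check all invariants (default `TRUE`).
#' @return An object of class `"session_log"`.
#' @seealso [load_session()], [save_session()], [simulate_cage()]
#' @export
session_log <- function(trials, entries, trajectories = list(),
                        metadata = list(), validate = TRUE) {
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"trajectory_ref" %in% names(trials) && nrow(trials) > 0) {
    trials$trajectory_ref <- NA_character_
  }
  if (nrow(trials) > 0) trials <- trials[order(trials$t_start), , drop = FALSE]
  rownames(trials) <- NULL
  rownames(entries) <- NULL
  log <- structure(list(trials = trials, entries = entries,
                        trajectories = trajectories, metadata = metadata),
                   class = "session_log")
  if (validate) validate_session_log(log)
  log
}

trial_cols <- c("trial_id", "mouse_id", "entry_id", "t_start", "stage",
                "required_hold_time", "hold_time", "success")
entry_cols <- c("entry_id", "mouse_id", "t_enter", "t_exit")

#' Validate a session log against its invariants
#'
#' Checks field presence, value ranges, per-mouse strictly increasing trial
#' times, non-overlapping entries, referential integrity of `entry_id` and
#' `trajectory_ref`, the stage-dependent success rule and genotype coverage.
#' Violations raise an error listing the offending record ids.
#'
#' @param log A [session_log()].
#' @return `log`, invisibly, if valid.
#' @export
validate_session_log <- function(log) {
  stopifnot(inherits(log, "session_log"))
  trials <- log$trials; entries <- log$entries
  problems <- character()
  miss <- setdiff(trial_cols, names(trials))
  if (nrow(trials) > 0 && length(miss)) {
    stop("trials is missing columns: ", paste(miss, collapse = ", "))
  }
  miss <- setdiff(entry_cols, names(entries))
  if (nrow(entries) > 0 && length(miss)) {
    stop("entries is missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(trials) > 0) {
    bad <- trials$trial_id[is.na(trials$hold_time) | trials$hold_time < 0]
    if (length(bad)) problems <- c(problems, paste0(
      "negative hold_time: ", paste(bad, collapse = ", ")))
    bad <- trials$trial_id[is.na(trials$required_hold_time) |
                             trials$required_hold_time < 0 |
                             trials$required_hold_time > 1]
    if (length(bad)) problems <- c(problems, paste0(
      "required_hold_time outside [0, 1]: ", paste(bad, collapse = ", ")))
    bad <- trials$trial_id[!trials$stage %in% c(1L, 2L)]
    if (length(bad)) problems <- c(problems, paste0(
      "stage not in {1, 2}: ", paste(bad, collapse = ", ")))
    s2 <- trials$stage == 2
    bad <- trials$trial_id[s2 & (trials$success !=
                                   (trials$hold_time >= trials$required_hold_time))]
    if (length(bad)) problems <- c(problems, paste0(
      "stage-2 success inconsistent with hold_time >= required: ",
      paste(bad, collapse = ", ")))
    bad <- trials$trial_id[!s2 & !trials$success]
    if (length(bad)) problems <- c(problems, paste0(
      "stage-1 trials must be successful: ", paste(bad, collapse = ", ")))
    for (m in unique(trials$mouse_id)) {
      ts <- trials$t_start[trials$mouse_id == m]
      if (any(diff(ts) <= 0)) {
        problems <- c(problems, paste0(
          "t_start not strictly increasing for mouse ", m))
      }
    }
    if (nrow(entries) > 0 || nrow(trials) > 0) {
      bad <- trials$trial_id[!trials$entry_id %in% entries$entry_id]
      if (length(bad)) problems <- c(problems, paste0(
        "unknown entry_id for trials: ", paste(bad, collapse = ", "),
        " (entry ids: ",
        paste(unique(trials$entry_id[!trials$entry_id %in% entries$entry_id]),
              collapse = ", "), ")"))
    }
    refs <- trials$trajectory_ref
    refs <- refs[!is.na(refs)]
    bad <- refs[!refs %in% names(log$trajectories)]
    if (length(bad)) problems <- c(problems, paste0(
      "unresolved trajectory_ref: ", paste(bad, collapse = ", ")))
    gm <- log$metadata$genotypes
    if (!is.null(gm)) {
      bad <- setdiff(unique(trials$mouse_id), names(gm))
      if (length(bad)) problems <- c(problems, paste0(
        "mouse missing from genotype map: ", paste(bad, collapse = ", ")))
    }
  }
  if (nrow(entries) > 0) {
    bad <- entries$entry_id[entries$t_exit <= entries$t_enter]
    if (length(bad)) problems <- c(problems, paste0(
      "t_exit <= t_enter for entries: ", paste(bad, collapse = ", ")))
    for (m in unique(entries$mouse_id)) {
      e <- entries[entries$mouse_id == m, , drop = FALSE]
      e <- e[order(e$t_enter), , drop = FALSE]
      if (nrow(e) > 1 && any(e$t_enter[-1] < e$t_exit[-nrow(e)])) {
        problems <- c(problems, paste0("overlapping entries for mouse ", m))
      }
    }
  }
  for (tr in log$trajectories) {
    if (!inherits(tr, "trajectory")) {
      problems <- c(problems, "trajectories must contain trajectory objects")
      break
    }
  }
  if (length(problems)) {
    stop("session log validation failed:\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(log)
}

#' @export
print.session_log <- function(x, ...) {
  nm <- unique(x$trials$mouse_id)
  days <- if (nrow(x$trials)) {
    max(floor(x$trials$t_start / 86400)) + 1L
  } else 0L
  cat("<session_log> cage", x$metadata$cage_id %||% "?", "\n")
  cat("  ", nrow(x$trials), " trials, ", nrow(x$entries), " entries, ",
      length(x$trajectories), " trajectories\n", sep = "")
  cat("  ", length(nm), " mice (",
      paste(head(nm, 6), collapse = ", "), "), spanning ", days,
      " day(s)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt17 <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- ""
  out
}

write_csv_exact <- function(df, path, num_cols) {
  out <- df
  for (cl in num_cols) out[[cl]] <- fmt17(df[[cl]])
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
}

#' Save a session log to a directory
#'
#' Writes `trials.csv` (`success` encoded 0/1), `entries.csv`,
#' `metadata.yaml` and one `trajectories/<trial_id>.csv` per trajectory
#' (columns `t_s`, `angle_deg`). Numeric fields are written with 17
#' significant digits so a save/load round trip reproduces the log exactly,
#' and output bytes are deterministic.
#'
#' @param log A valid [session_log()].
#' @param path Directory to write into (created if needed).
#' @return `path`, invisibly.
#' @export
save_session <- function(log, path) {
  validate_session_log(log)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  trials <- log$trials
  if (nrow(trials) == 0) {
    trials <- data.frame(trial_id = character(), mouse_id = character(),
                         entry_id = character(), t_start = numeric(),
                         stage = integer(), required_hold_time = numeric(),
                         hold_time = numeric(), success = integer(),
                         trajectory_ref = character())
  } else {
    trials <- trials[, c(trial_cols, "trajectory_ref")]
    trials$success <- as.integer(trials$success)
  }
  write_csv_exact(trials, file.path(path, "trials.csv"),
                  c("t_start", "required_hold_time", "hold_time"))
  entries <- log$entries
  if (nrow(entries) == 0) {
    entries <- data.frame(entry_id = character(), mouse_id = character(),
                          t_enter = numeric(), t_exit = numeric())
  } else {
    entries <- entries[, entry_cols]
  }
  write_csv_exact(entries, file.path(path, "entries.csv"),
                  c("t_enter", "t_exit"))
  md <- log$metadata
  yaml::write_yaml(list(cage_id = md$cage_id %||% "cage",
                        day0 = md$day0 %||% "1970-01-01",
                        genotypes = as.list(md$genotypes %||%
                                              stats::setNames(character(), character()))),
                   file.path(path, "metadata.yaml"))
  tdir <- file.path(path, "trajectories")
  if (length(log$trajectories)) {
    dir.create(tdir, showWarnings = FALSE)
    for (tr in log$trajectories) {
      n <- length(tr$angle)
      write_csv_exact(
        data.frame(t_s = (seq_len(n) - 1) / tr$fs, angle_deg = tr$angle),
        file.path(tdir, paste0(tr$trial_id, ".csv")),
        c("t_s", "angle_deg"))
    }
  }
  invisible(path)
}

#' Load a session log from a directory
#'
#' Reads the on-disk layout written by [save_session()] and returns a
#' validated [session_log()] with trials sorted by `t_start`. A missing file
#' raises a load error naming the file; invariant violations raise a
#' validation error listing the offending record ids.
#'
#' @param path Directory containing `trials.csv`, `entries.csv`,
#'   `metadata.yaml` and optionally `trajectories/`.
#' @return A [session_log()].
#' @export
load_session <- function(path) {
  for (f in c("trials.csv", "entries.csv", "metadata.yaml")) {
    if (!file.exists(file.path(path, f))) {
      stop("load error: missing file '", f, "' in ", path)
    }
  }
  trials <- read.csv(file.path(path, "trials.csv"),
                     colClasses = c(trial_id = "character",
                                    mouse_id = "character",
                                    entry_id = "character",
                                    trajectory_ref = "character"))
  if (nrow(trials)) {
    trials$success <- as.logical(trials$success)
    trials$stage <- as.integer(trials$stage)
    trials$trajectory_ref[!nzchar(trials$trajectory_ref) |
                            is.na(trials$trajectory_ref)] <- NA_character_
  }
  entries <- read.csv(file.path(path, "entries.csv"),
                      colClasses = c(entry_id = "character",
                                     mouse_id = "character"))
  md <- yaml::read_yaml(file.path(path, "metadata.yaml"))
  md$genotypes <- unlist(md$genotypes) %||% stats::setNames(character(), character())
  tdir <- file.path(path, "trajectories")
  trajs <- list()
  if (dir.exists(tdir)) {
    files <- sort(list.files(tdir, pattern = "\\.csv$"))
    for (f in files) {
      id <- sub("\\.csv$", "", f)
      d <- read.csv(file.path(tdir, f))
      trajs[[id]] <- trajectory(id, d$angle_deg)
    }
  }
  session_log(trials, entries, trajs, md)
}

#' Calendar day index of a session timestamp
#'
#' Days are counted from the session epoch (midnight of `day0`); day 1 spans
#' the first 86400 s. The scheduler updates at these midnight boundaries.
#'
#' @param t Numeric vector of timestamps in seconds since the session epoch.
#' @return Integer vector of 1-based day indices.
#' @export
day_of <- function(t) as.integer(floor(t / 86400)) + 1L
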