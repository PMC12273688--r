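.LOG_COLUMNS <- c("participant_id", "trial", "unit", "pair", "choice",
                  "rewarded", "pending_before", "points_cum")

#' Write a session log as CSV
#'
#' One row per trial with the documented columns `participant_id`, `trial`,
#' `unit`, `pair`, `choice`, `rewarded`, `pending_before`, `points_cum`.
#'
#' @param log A `session_log`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  df <- cbind(participant_id = log$participant_id, log$trials)
  names(df) <- .LOG_COLUMNS
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a session log CSV
#'
#' Re-checks every trial-record invariant on load: contiguous 1-based trial
#' indices, choices belonging to the presented pair, no immediate reward on
#' CD trials, AB rewards exactly for A choices, pending-queue depth in
#' 0..2, and a consistent cumulative-points column. Early termination is
#' inferred: a session counts as terminated iff the learning criterion
#' completes exactly at its last trial (a CD trial) and the log is shorter
#' than its full length would be.
#'
#' @param path CSV file written by [write_session_log()].
#' @param config Optional [session_config()]; if `NULL` one is
#'   reconstructed with `n_units` taken from the data.
#' @return A `session_log`.
#' @export
read_session_log <- function(path, config = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty session log: ", path)
  missing_cols <- setdiff(.LOG_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))

  fail <- function(i, msg) stop("row ", i, ": ", msg)
  n <- nrow(df)
  if (!identical(as.integer(df$trial), seq_len(n)))
    stop("trial indices are not contiguous from 1")
  for (i in seq_len(n)) {
    if (!df$pair[i] %in% TRIAL_TYPES) fail(i, "unknown pair")
    if (!df$choice[i] %in% pair_roles(df$pair[i]))
      fail(i, sprintf("choice %s outside pair %s", df$choice[i], df$pair[i]))
    if (!df$rewarded[i] %in% c(0L, 1L)) fail(i, "rewarded must be 0/1")
    if (df$pair[i] == "CD" && df$rewarded[i] == 1L)
      fail(i, "CD trial with immediate reward")
    if (df$pair[i] == "AB" && df$rewarded[i] != as.integer(df$choice[i] == "A"))
      fail(i, "AB reward inconsistent with choice")
    if (df$pending_before[i] < 0L || df$pending_before[i] > 2L)
      fail(i, "pending_before outside 0..2")
  }
  if (!identical(as.integer(df$points_cum), cumsum(as.integer(df$rewarded))))
    stop("points_cum is not the running sum of rewarded")

  if (is.null(config))
    config <- session_config(n_units = max(df$unit))
  cd <- df$choice[df$pair == "CD"]
  crit <- detect_criterion(cd, "C", config$bin_size,
                           config$criterion_threshold,
                           config$criterion_consecutive_bins)
  cd_rows <- which(df$pair == "CD")
  terminated <- isTRUE(crit$met) &&
    !is.na(crit$completing_trial) &&
    cd_rows[crit$completing_trial] == n &&
    n < 3L * config$n_units
  structure(
    list(
      config = config,
      trials = df[, setdiff(.LOG_COLUMNS, "participant_id")],
      terminated_early = terminated,
      termination_trial = if (terminated) n else NA_integer_,
      participant_id = df$participant_id[1],
      agent_meta = ""
    ),
    class = "session_log"
  )
}

#' Write a cohort to a directory
#'
#' One session-log CSV per participant plus a `labels.csv`
#' (`participant_id`, `archetype`, `seed`).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (log in cohort$logs)
    write_session_log(log, file.path(dir, paste0(log$participant_id, ".csv")))
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir Directory written by [write_cohort()].
#' @param config Optional shared [session_config()] passed to
#'   [read_session_log()].
#' @return A `cohort` (labels present only if `labels.csv` exists).
#' @export
read_cohort <- function(dir, config = NULL) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[basename(files) != "labels.csv"]
  if (length(files) == 0L) stop("no session logs in ", dir)
  logs <- lapply(files, read_session_log, config = config)
  names(logs) <- vapply(logs, function(l) l$participant_id, character(1))
  labels_path <- file.path(dir, "labels.csv")
  labels <- if (file.exists(labels_path))
    utils::read.csv(labels_path, stringsAsFactors = FALSE) else NULL
  structure(list(logs = logs, labels = labels), class = "cohort")
}

#' Write a session configuration as JSON
#' @param config A [session_config()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a session configuration from JSON
#'
#' Keys must mirror the [session_config()] field names exactly; unknown
#' keys are errors.
#'
#' @param path JSON file.
#' @return A `session_config`.
#' @export
read_session_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(session_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(session_config, x)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a scripted run byte-for-byte:
#' the command name, the fully resolved configuration, the master seed and
#' derived per-session seeds, the package version and a timestamp.
#'
#' @param path Output JSON path.
#' @param command Short command name (e.g. `"simulate-grid"`).
#' @param config A list (or config object) of resolved settings.
#' @param master_seed Integer master seed.
#' @param session_seeds Integer vector of derived per-session seeds.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config, master_seed,
                               session_seeds = integer(0)) {
  manifest <- list(
    command = command,
    config = if (is.list(config)) unclass(config) else config,
    master_seed = as.integer(master_seed),
    session_seeds = as.integer(session_seeds),
    package_version = as.character(utils::packageVersion("delaycredit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}
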