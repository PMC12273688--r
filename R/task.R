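#' @keywords internal
"_PACKAGE"

## Trial types and stimulus roles. Each trial presents one ordered pair:
## AB (A rewarded immediately), CD (never rewarded immediately; C queues a
## delayed reward), EF (pays out the oldest pending C/D outcome).
TRIAL_TYPES <- c("AB", "CD", "EF")
ROLES <- c("A", "B", "C", "D", "E", "F")

## the 6 orderings of the three trial types within a unit
.UNIT_PERMS <- rbind(
  c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
)

#' Stimulus pair presented on a trial type
#'
#' @param trial_type One of `"AB"`, `"CD"`, `"EF"`.
#' @return Character vector of the two stimulus roles, first option first.
#' @export
#' @examples
#' pair_roles("CD")
pair_roles <- function(trial_type) {
  switch(trial_type,
    AB = c("A", "B"), CD = c("C", "D"), EF = c("E", "F"),
    stop("unknown trial type: ", trial_type)
  )
}

#' Trial type owning a stimulus role
#' @param role One of `"A"` ... `"F"`.
#' @return The trial type (`"AB"`, `"CD"` or `"EF"`) whose pair contains `role`.
#' @export
role_pair <- function(role) {
  i <- match(role, ROLES)
  if (is.na(i)) stop("unknown stimulus role: ", role)
  TRIAL_TYPES[(i + 1L) %/% 2L]
}

#' Session configuration
#'
#' Describes one session of the delayed-feedback task: how many three-trial
#' units are presented, and the learning criterion that can terminate the
#' session early (at least `criterion_threshold` target choices out of
#' `bin_size` consecutive same-pair trials, for `criterion_consecutive_bins`
#' consecutive non-overlapping bins counted from the session start).
#'
#' @param n_units Number of three-trial units (default 167, i.e. 501 trials).
#' @param bin_size Trials per criterion bin (default 10).
#' @param criterion_threshold Minimum target choices per qualifying bin
#'   (default 8). Must not exceed `bin_size`.
#' @param criterion_consecutive_bins Number of consecutive qualifying bins
#'   required (default 2).
#' @param termination_enabled Should the session stop at the trial completing
#'   the criterion? Default `TRUE` (as in the behavioral experiment);
#'   simulation grids run with `FALSE`.
#' @param seed Optional integer seed giving the session its own reproducible
#'   random stream (sequence generation and any stochastic policy).
#' @return An object of class `session_config`.
#' @export
#' @examples
#' session_config()                      # the 501-trial default session
#' session_config(n_units = 160, termination_enabled = FALSE)
session_config <- function(n_units = 167L, bin_size = 10L,
                           criterion_threshold = 8L,
                           criterion_consecutive_bins = 2L,
                           termination_enabled = TRUE, seed = NULL) {
  n_units <- as.integer(n_units)
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1L)
    stop("n_units must be a positive integer")
  bin_size <- as.integer(bin_size)
  criterion_threshold <- as.integer(criterion_threshold)
  criterion_consecutive_bins <- as.integer(criterion_consecutive_bins)
  if (bin_size < 1L) stop("bin_size must be a positive integer")
  if (criterion_threshold < 1L || criterion_threshold > bin_size)
    stop("criterion_threshold must be in 1..bin_size")
  if (criterion_consecutive_bins < 1L)
    stop("criterion_consecutive_bins must be a positive integer")
  structure(
    list(
      n_units = n_units, bin_size = bin_size,
      criterion_threshold = criterion_threshold,
      criterion_consecutive_bins = criterion_consecutive_bins,
      termination_enabled = isTRUE(termination_enabled),
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "session_config"
  )
}

#' Generate a quasi-random trial-type sequence
#'
#' The sequence is built from units of three trials, one of each type, with
#' the within-unit order drawn uniformly over all six orderings and
#' independently across units. This structure guarantees that at most two
#' CD trials ever separate consecutive EF trials, bounding the pending
#' delayed-reward queue at depth 2.
#'
#' @param n_units Number of units (each contributes 3 trials).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return Character vector of length `3 * n_units` with values in
#'   `c("AB", "CD", "EF")`.
#' @export
#' @examples
#' generate_sequence(2, seed = 1)
generate_sequence <- function(n_units, seed = NULL) {
  n_units <- as.integer(n_units)
  if (length(n_units) != 1L || is.na(n_units) || n_units < 1L)
    stop("n_units must be a positive integer")
  if (!is.null(seed)) set.seed(as.integer(seed))
  perm <- sample.int(6L, n_units, replace = TRUE)
  TRIAL_TYPES[as.vector(t(.UNIT_PERMS[perm, , drop = FALSE]))]
}

#' Pending-outcome depth before each trial
#'
#' For each trial of a sequence, the number of CD trials whose outcome has
#' not yet been delivered at an EF trial (equivalently, the depth of the
#' delayed-reward queue just before the trial, under any policy). The unit
#' structure bounds this at 2.
#'
#' @param types Character vector of trial types, as from [generate_sequence()].
#' @return Integer vector, same length as `types`.
#' @export
#' @examples
#' pending_depth_profile(c("CD", "EF", "AB"))
pending_depth_profile <- function(types) {
  depth <- 0L
  out <- integer(length(types))
  for (i in seq_along(types)) {
    out[i] <- depth
    if (types[i] == "CD") depth <- depth + 1L
    else if (types[i] == "EF" && depth > 0L) depth <- depth - 1L
  }
  out
}

#' Run one session of the delayed-feedback task
#'
#' Presents a generated trial sequence to a choice policy and applies the
#' reward rules: A is rewarded immediately, B never; CD trials are never
#' rewarded immediately but enqueue the choice (C = `TRUE`, D = `FALSE`)
#' onto a FIFO queue of pending outcomes; each EF trial dequeues the oldest
#' entry (if any) and is rewarded iff that entry was a C choice. An EF trial
#' reached with an empty queue pays 0. If `config$termination_enabled`, the
#' session ends at the CD trial that completes the second consecutive
#' qualifying criterion bin.
#'
#' @param policy A function `(trial_type, history) -> role` returning one of
#'   the two roles of the presented pair. `history` is a list with element
#'   `n` (number of completed trials) and vectors `trial_type`, `choice`,
#'   `rewarded`, `pending_before` whose first `n` entries describe the
#'   completed trials in order.
#' @param config A [session_config()].
#' @param participant_id Label stored in the log.
#' @param agent_meta Free-form text describing the generating policy.
#' @param types Optional explicit trial-type sequence, overriding
#'   generation from `config` (useful for scripted scenarios).
#' @return An object of class `session_log`: a list with elements `config`,
#'   `trials` (data frame with one row per presented trial), flags
#'   `terminated_early` / `termination_trial`, `participant_id`, `agent_meta`.
#' @export
#' @examples
#' always_c <- function(trial_type, history) pair_roles(trial_type)[1]
#' log <- run_session(always_c, session_config(n_units = 5, seed = 1))
#' log$trials
run_session <- function(policy, config = session_config(),
                        participant_id = "anon", agent_meta = "",
                        types = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(types)) {
    types <- generate_sequence(config$n_units)
  } else if (!all(types %in% TRIAL_TYPES)) {
    stop("types must be a vector of trial types")
  }
  n <- length(types)

  choice <- character(n)
  rewarded <- integer(n)
  pending_before <- integer(n)
  cum <- integer(n)
  queue <- logical(n)   # FIFO of pending CD outcomes (TRUE = C chosen)
  q_head <- 1L; q_tail <- 0L

  points <- 0L
  cd_n <- 0L; cd_in_bin <- 0L; qual_run <- 0L
  terminated <- FALSE; term_trial <- NA_integer_
  i <- 0L

  while (i < n) {
    i <- i + 1L
    tt <- types[i]
    pending_before[i] <- q_tail - q_head + 1L
    hist <- list(
      n = i - 1L, trial_type = types, choice = choice,
      rewarded = rewarded, pending_before = pending_before
    )
    ch <- policy(tt, hist)
    if (length(ch) != 1L || !ch %in% pair_roles(tt))
      stop("policy returned '", ch, "' for a ", tt, " trial")
    choice[i] <- ch
    r <- 0L
    if (tt == "AB") {
      r <- as.integer(ch == "A")
    } else if (tt == "CD") {
      q_tail <- q_tail + 1L
      queue[q_tail] <- (ch == "C")
    } else { # EF: consume the oldest pending outcome, if any
      if (q_head <= q_tail) {
        r <- as.integer(queue[q_head])
        q_head <- q_head + 1L
      }
    }
    rewarded[i] <- r
    points <- points + r
    cum[i] <- points

    if (tt == "CD") {
      cd_n <- cd_n + 1L
      cd_in_bin <- cd_in_bin + as.integer(ch == "C")
      if (cd_n %% config$bin_size == 0L) {
        qual_run <- if (cd_in_bin >= config$criterion_threshold) qual_run + 1L else 0L
        cd_in_bin <- 0L
        if (qual_run >= config$criterion_consecutive_bins &&
            config$termination_enabled) {
          terminated <- TRUE
          term_trial <- i
          break
        }
      }
    }
  }

  keep <- seq_len(i)
  trials <- data.frame(
    trial = keep,
    unit = (keep + 2L) %/% 3L,
    pair = types[keep],
    choice = choice[keep],
    rewarded = rewarded[keep],
    pending_before = pending_before[keep],
    points_cum = cum[keep],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      config = config, trials = trials,
      terminated_early = terminated, termination_trial = term_trial,
      participant_id = participant_id, agent_meta = agent_meta
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat(sprintf(
    "<session_log> %s: %d trials (%d units)%s\n  %s\n",
    x$participant_id, nrow(x$trials), x$config$n_units,
    if (x$terminated_early)
      sprintf(", terminated at trial %d", x$termination_trial) else "",
    if (nzchar(x$agent_meta)) x$agent_meta else "scripted policy"
  ))
  invisible(x)
}

#' Choice-to-outcome lags of delivered delayed rewards
#'
#' For every CD trial whose queued outcome was delivered at a later EF trial,
#' the trial-index difference between the paying EF trial and the originating
#' CD trial. Outcomes still pending at session end are omitted. Under the
#' unit structure every lag lies in 1..5 and the mean is close to 3 trials.
#'
#' @param log A `session_log`.
#' @return Integer vector of lags (possibly empty).
#' @export
lag_distribution <- function(log) {
  stopifnot(inherits(log, "session_log"))
  tr <- log$trials
  cd_idx <- integer(0)
  lags <- integer(0)
  for (i in seq_len(nrow(tr))) {
    if (tr$pair[i] == "CD") {
      cd_idx <- c(cd_idx, i)
    } else if (tr$pair[i] == "EF" && length(cd_idx) > 0L) {
      lags <- c(lags, i - cd_idx[1L])
      cd_idx <- cd_idx[-1L]
    }
  }
  lags
}
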