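ARCHETYPES <- c("c_learner", "d_perseverator", "e_superstitious",
                "f_superstitious", "random_chooser", "immediate_only")

## Stylized stand-ins for the heterogeneous response patterns seen in human
## cohorts on this task. Probabilities are artifact parameters (not measured
## values) chosen so each classification criterion is exercised with high
## power over a 167-unit session. p_C may be a step ramp emulating a
## participant who discovers the delayed contingency mid-session.
.ARCHETYPE_DEFAULTS <- list(
  c_learner       = list(p_A = 0.95, p_C = list(start = 0.5, end = 0.95, switch = 30L), p_E = 0.5),
  d_perseverator  = list(p_A = 0.95, p_C = 0.15, p_E = 0.5),
  e_superstitious = list(p_A = 0.95, p_C = 0.5,  p_E = 0.9),
  f_superstitious = list(p_A = 0.95, p_C = 0.5,  p_E = 0.1),
  random_chooser  = list(p_A = 0.5,  p_C = 0.5,  p_E = 0.5),
  immediate_only  = list(p_A = 0.95, p_C = 0.5,  p_E = 0.5)
)

#' Behavioral archetype specification
#'
#' A scripted participant: independent Bernoulli choices with per-pair
#' probabilities `p_A` (choosing A on AB trials), `p_C` (choosing C on CD
#' trials; optionally a step ramp `list(start, end, switch)` applied by
#' CD-trial ordinal, so the probability jumps from `start` to `end` after
#' the `switch`-th CD trial) and `p_E` (choosing E on EF trials).
#'
#' Named archetypes default to: `c_learner` (rapid A learning, C ramping
#' 0.5 to 0.95 after CD trial 30, typically hitting the termination
#' criterion), `d_perseverator` (strong D bias, p_C = 0.15),
#' `e_superstitious` / `f_superstitious` (strong E or F bias, p_E = 0.9 /
#' 0.1), `random_chooser` (all 0.5) and `immediate_only` (learns A only).
#'
#' @param name One of the six archetype names.
#' @param p_A,p_C,p_E Override the archetype's default probabilities.
#' @return An object of class `archetype_spec`.
#' @export
#' @examples
#' archetype_spec("d_perseverator")
archetype_spec <- function(name = ARCHETYPES, p_A = NULL, p_C = NULL,
                           p_E = NULL) {
  name <- match.arg(name)
  d <- .ARCHETYPE_DEFAULTS[[name]]
  if (!is.null(p_A)) d$p_A <- p_A
  if (!is.null(p_C)) d$p_C <- p_C
  if (!is.null(p_E)) d$p_E <- p_E
  chk <- function(p) {
    ps <- if (is.list(p)) c(p$start, p$end) else p
    if (any(ps < 0 | ps > 1)) stop("choice probabilities must lie in [0, 1]")
  }
  chk(d$p_A); chk(d$p_C); chk(d$p_E)
  structure(list(name = name, p_A = d$p_A, p_C = d$p_C, p_E = d$p_E),
            class = "archetype_spec")
}

#' Choice policy of a behavioral archetype
#'
#' @param spec An [archetype_spec()].
#' @return A policy function `(trial_type, history) -> role` for
#'   [run_session()], drawing each choice independently with the spec's
#'   probabilities (the `p_C` ramp is applied by CD-trial count).
#' @export
archetype_policy <- function(spec) {
  stopifnot(inherits(spec, "archetype_spec"))
  cd_n <- 0L
  function(trial_type, history) {
    if (trial_type == "AB") {
      if (stats::runif(1) < spec$p_A) "A" else "B"
    } else if (trial_type == "CD") {
      cd_n <<- cd_n + 1L
      p <- spec$p_C
      if (is.list(p)) p <- if (cd_n <= p$switch) p$start else p$end
      if (stats::runif(1) < p) "C" else "D"
    } else {
      if (stats::runif(1) < spec$p_E) "E" else "F"
    }
  }
}

#' Counter-based per-session seed derivation
#'
#' Derives the i-th session seed deterministically from a master seed, so
#' adding or removing participants from a cohort never reshuffles the
#' random streams of the ones already there.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of `n` seeds in 1 .. 2^31 - 2.
#' @export
derive_seeds <- function(master_seed, n) {
  i <- seq_len(n)
  as.integer((as.double(master_seed) %% 2147483647 + i * 1000003) %% 2147483646 + 1)
}

#' Cohort specification
#'
#' @param composition Named integer vector mapping archetype names to
#'   participant counts, e.g. `c(c_learner = 9, random_chooser = 5)`.
#' @param config A [session_config()] shared by all participants
#'   (termination enabled by default, as in the behavioral experiment).
#' @param master_seed Integer; per-participant seeds are derived from it
#'   with [derive_seeds()].
#' @param archetypes Optional named list of [archetype_spec()] overrides.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(composition, config = session_config(),
                        master_seed = 1L, archetypes = NULL) {
  if (length(composition) > 0) {
    if (is.null(names(composition)) || !all(names(composition) %in% ARCHETYPES))
      stop("composition must be named by archetype")
    if (any(composition < 0)) stop("composition counts must be >= 0")
  }
  structure(
    list(composition = composition, config = config,
         master_seed = as.integer(master_seed), archetypes = archetypes),
    class = "cohort_spec"
  )
}

#' Generate a labelled synthetic cohort
#'
#' Runs one session per participant through [run_session()] (with the
#' spec's session config) and keeps the ground-truth archetype label with
#' each log, so classification can be scored against truth. Fully
#' reproducible from the master seed.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `cohort`: list with `logs` (named list of
#'   `session_log`) and `labels` (data frame `participant_id`, `archetype`,
#'   `seed`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(
#'   c(c_learner = 2, random_chooser = 2),
#'   config = session_config(n_units = 40), master_seed = 7
#' ))
#' coh$labels
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  comp <- spec$composition
  total <- if (length(comp)) sum(comp) else 0L
  seeds <- derive_seeds(spec$master_seed, total)
  logs <- list()
  labels <- data.frame(participant_id = character(0),
                       archetype = character(0), seed = integer(0),
                       stringsAsFactors = FALSE)
  k <- 0L
  for (arch in names(comp)) {
    aspec <- if (!is.null(spec$archetypes[[arch]])) spec$archetypes[[arch]]
             else archetype_spec(arch)
    for (j in seq_len(comp[[arch]])) {
      k <- k + 1L
      pid <- sprintf("%s_%02d", arch, j)
      cfg <- spec$config
      cfg$seed <- seeds[k]
      logs[[pid]] <- run_session(archetype_policy(aspec), cfg,
                                 participant_id = pid,
                                 agent_meta = paste0("archetype=", arch))
      labels <- rbind(labels, data.frame(
        participant_id = pid, archetype = arch, seed = seeds[k],
        stringsAsFactors = FALSE
      ))
    }
  }
  structure(list(logs = logs, labels = labels), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants: %s\n", nrow(x$labels),
              paste(sprintf("%s=%d", names(table(x$labels$archetype)),
                            table(x$labels$archetype)), collapse = ", ")))
  invisible(x)
}
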