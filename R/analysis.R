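#' Exponentially weighted end-of-session choice rate
#'
#' Weighted average of a 0/1 choice-indicator series over its last
#' `window` entries, with weight `decay^tau` on the entry `tau` steps
#' before the end and weights normalized to sum 1:
#' `sum(decay^tau * x[T - tau]) / sum(decay^tau)`, `tau = 0 .. w - 1`.
#' Series shorter than the window use all available entries with
#' renormalized weights.
#'
#' @param x 0/1 (or logical) indicator series in presentation order.
#' @param decay Weight decay per step back, in (0, 1); default 0.9.
#' @param window Number of most recent entries used; default 30.
#' @return A value in \[0, 1\].
#' @export
#' @examples
#' weighted_choice_rate(rep(1, 40))       # 1
#' weighted_choice_rate(c(rep(0, 20), rep(1, 20)))
weighted_choice_rate <- function(x, decay = 0.9, window = 30L) {
  x <- as.numeric(x)
  if (length(x) == 0L) stop("empty indicator series")
  if (!(decay > 0 && decay < 1)) stop("decay must be in (0, 1)")
  w <- min(as.integer(window), length(x))
  if (w < 1L) stop("window must be a positive integer")
  tail_x <- x[(length(x) - w + 1L):length(x)]
  wt <- decay^((w - 1L):0L)   # tau = 0 at the last entry
  sum(wt * tail_x) / sum(wt)
}

#' End-of-session choice rates of A, C and E
#'
#' Computes the weighted choice rates P_A, P_C, P_E over the last `window`
#' trials of each pair type (windows run within a trial type, not over the
#' interleaved session).
#'
#' @param log A `session_log`.
#' @inheritParams weighted_choice_rate
#' @return Named list with `p_A`, `p_C`, `p_E`.
#' @export
choice_rates <- function(log, decay = 0.9, window = 30L) {
  tr <- log$trials
  rate <- function(pair, role) {
    ind <- tr$choice[tr$pair == pair] == role
    if (length(ind) == 0L) return(NA_real_)
    weighted_choice_rate(ind, decay, window)
  }
  list(p_A = rate("AB", "A"), p_C = rate("CD", "C"), p_E = rate("EF", "E"))
}

#' Detect the consecutive-bin learning criterion
#'
#' Partitions the same-pair choice series into non-overlapping bins of
#' `bin_size` counted from the session start; the criterion is met iff some
#' `n_consecutive` successive full bins each contain at least `threshold`
#' target choices. A trailing partial bin never qualifies.
#'
#' @param choices Character vector of choices on the trials of one pair
#'   type, in presentation order.
#' @param target The role counted (e.g. `"C"` or `"D"`).
#' @param bin_size,threshold,n_consecutive Criterion parameters
#'   (defaults 10, 8, 2).
#' @return A list of class `criterion_result`: `met`, `completing_trial`
#'   (the same-pair trial ordinal ending the last qualifying bin, or `NA`),
#'   `qualifying_bins` (pair of bin indices, or `NULL`).
#' @export
#' @examples
#' detect_criterion(rep("C", 20), "C")   # met at CD trial 20
detect_criterion <- function(choices, target, bin_size = 10L,
                             threshold = 8L, n_consecutive = 2L) {
  n_bins <- length(choices) %/% bin_size
  met <- FALSE; completing <- NA_integer_; bins <- NULL
  if (n_bins >= n_consecutive) {
    counts <- vapply(seq_len(n_bins), function(b) {
      sum(choices[((b - 1L) * bin_size + 1L):(b * bin_size)] == target)
    }, integer(1))
    qual <- counts >= threshold
    run <- 0L
    for (b in seq_len(n_bins)) {
      run <- if (qual[b]) run + 1L else 0L
      if (run >= n_consecutive) {
        met <- TRUE
        completing <- b * bin_size
        bins <- c(b - n_consecutive + 1L, b)
        break
      }
    }
  }
  structure(list(met = met, completing_trial = completing,
                 qualifying_bins = bins),
            class = "criterion_result")
}

#' Exact binomial test of overall choice bias
#'
#' Two-sided exact binomial test of `n_target` successes in `n_total`
#' trials against probability 0.5, with the two-sided p-value computed by
#' the point-probability method (summing all outcomes no more likely than
#' the observed count).
#'
#' @param n_target Number of target choices.
#' @param n_total Number of trials of the pair.
#' @return List with `fraction` and `p_value`.
#' @export
overall_bias_test <- function(n_target, n_total) {
  if (n_total < 1L || n_target < 0L || n_target > n_total)
    stop("need 0 <= n_target <= n_total, n_total >= 1")
  list(fraction = n_target / n_total,
       p_value = stats::binom.test(n_target, n_total, p = 0.5)$p.value)
}

#' Chi-square test of a choice-rate change between session halves
#'
#' 2x2 chi-square test of independence (halves x choice) with continuity
#' correction by default. If a choice column margin is zero (the
#' participant chose only one option throughout) the test is undefined and
#' p = 1 is returned with `degenerate = TRUE`.
#'
#' @param first_half,second_half Length-2 counts `c(n_target, n_other)`
#'   for each half.
#' @param correct Apply the continuity correction (default `TRUE`).
#' @return List with `direction` (`"increase"` iff the second-half target
#'   fraction exceeds the first-half fraction, else `"decrease"`),
#'   `p_value`, `statistic`, `degenerate`.
#' @export
halves_change_test <- function(first_half, second_half, correct = TRUE) {
  if (any(c(first_half, second_half) < 0) ||
      sum(first_half) == 0 || sum(second_half) == 0)
    stop("each half needs at least one trial")
  f1 <- first_half[1] / sum(first_half)
  f2 <- second_half[1] / sum(second_half)
  direction <- if (f2 > f1) "increase" else "decrease"
  m <- rbind(first_half, second_half)
  if (any(colSums(m) == 0)) {
    return(list(direction = direction, p_value = 1, statistic = 0,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(direction = direction, p_value = ct$p.value,
       statistic = unname(ct$statistic), degenerate = FALSE)
}

#' Fisher exact test of apparent immediate rewards after E vs F
#'
#' Tests whether delayed rewards happened to arrive more often immediately
#' after one of the two causally unrelated options, the driver of
#' superstitious bias. Builds the 2x2 table (choice E/F x rewarded yes/no)
#' and applies the two-sided Fisher exact test.
#'
#' @param ef_choices Character vector of E/F choices in presentation order.
#' @param ef_rewards Matching 0/1 rewards.
#' @return List with `direction` (`"E"` or `"F"`: the option with the
#'   higher observed reward rate; `"E"` on ties), `p_value` and `table`.
#' @export
immediate_reward_test <- function(ef_choices, ef_rewards) {
  if (length(ef_choices) == 0L) stop("empty E/F series")
  if (length(ef_choices) != length(ef_rewards))
    stop("choices and rewards must have equal length")
  if (!all(ef_choices %in% c("E", "F"))) stop("choices must be E or F")
  m <- matrix(c(
    sum(ef_choices == "E" & ef_rewards == 1),
    sum(ef_choices == "E" & ef_rewards == 0),
    sum(ef_choices == "F" & ef_rewards == 1),
    sum(ef_choices == "F" & ef_rewards == 0)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(choice = c("E", "F"), rewarded = c("yes", "no")))
  rate <- m[, 1] / pmax(rowSums(m), 1)
  direction <- if (rate["F"] > rate["E"]) "F" else "E"
  list(direction = direction, p_value = stats::fisher.test(m)$p.value,
       table = m)
}

#' Classify one participant on the six behavioral criteria
#'
#' Populates the per-participant classification row: (1) C learning
#' criterion, (2) D criterion (same bins, target D), (3) overall C-vs-D
#' binomial bias, (4) first-vs-second-half chi-square change in C choices
#' with direction, (5) overall E-vs-F binomial bias, (6) Fisher exact test
#' of apparent immediate rewards after E vs F. Significance is flagged at
#' two-tailed alpha 0.05 with no multiplicity adjustment. The halves split
#' divides the CD trials of the session at `ceiling(n/2)` by presentation
#' order. Cells whose test cannot be computed on a too-short log are `NA`.
#'
#' @param log A `session_log`.
#' @param report_category Externally supplied written-report category:
#'   `"full"`, `"partial"`, `"none"` or `"not_available"`.
#' @param correct Continuity correction for the halves chi-square.
#' @return One-row data frame (class `classification_record`).
#' @export
classify_participant <- function(log, report_category = "not_available",
                                 correct = TRUE) {
  stopifnot(inherits(log, "session_log"))
  report_category <- match.arg(report_category,
                               c("full", "partial", "none", "not_available"))
  tr <- log$trials
  cd <- tr$choice[tr$pair == "CD"]
  ef <- tr$choice[tr$pair == "EF"]
  ef_r <- tr$rewarded[tr$pair == "EF"]

  c_crit <- detect_criterion(cd, "C", log$config$bin_size,
                             log$config$criterion_threshold,
                             log$config$criterion_consecutive_bins)
  d_crit <- detect_criterion(cd, "D", log$config$bin_size,
                             log$config$criterion_threshold,
                             log$config$criterion_consecutive_bins)

  n_cd <- length(cd)
  if (n_cd >= 1L) {
    ob <- overall_bias_test(sum(cd == "C"), n_cd)
  } else ob <- list(fraction = NA_real_, p_value = NA_real_)

  half <- ceiling(n_cd / 2)
  if (n_cd >= 2L && half >= 1L && n_cd - half >= 1L) {
    h1 <- cd[seq_len(half)]; h2 <- cd[(half + 1L):n_cd]
    hv <- halves_change_test(c(sum(h1 == "C"), sum(h1 == "D")),
                             c(sum(h2 == "C"), sum(h2 == "D")),
                             correct = correct)
  } else hv <- list(direction = NA_character_, p_value = NA_real_,
                    statistic = NA_real_, degenerate = NA)

  if (length(ef) >= 1L) {
    eb <- overall_bias_test(sum(ef == "E"), length(ef))
    ir <- immediate_reward_test(ef, ef_r)
  } else {
    eb <- list(fraction = NA_real_, p_value = NA_real_)
    ir <- list(direction = NA_character_, p_value = NA_real_)
  }

  out <- data.frame(
    participant_id = log$participant_id,
    report_category = report_category,
    c_criterion_met = c_crit$met,
    c_criterion_trial = c_crit$completing_trial,
    d_criterion_met = d_crit$met,
    d_criterion_trial = d_crit$completing_trial,
    c_fraction = ob$fraction,
    c_binom_p = ob$p_value,
    c_binom_sig = !is.na(ob$p_value) & ob$p_value < 0.05,
    half_direction = hv$direction,
    half_chisq_p = hv$p_value,
    half_sig = !is.na(hv$p_value) & hv$p_value < 0.05,
    e_fraction = eb$fraction,
    ef_binom_p = eb$p_value,
    ef_binom_sig = !is.na(eb$p_value) & eb$p_value < 0.05,
    imm_reward_direction = ir$direction,
    imm_fisher_p = ir$p_value,
    imm_fisher_sig = !is.na(ir$p_value) & ir$p_value < 0.05,
    terminated_early = log$terminated_early,
    stringsAsFactors = FALSE
  )
  class(out) <- c("classification_record", "data.frame")
  out
}

#' Assemble the cohort classification table
#'
#' One [classify_participant()] row per participant, suitable for writing
#' as the analysis endpoint table.
#'
#' @param logs A `cohort` object or a (possibly named) list of
#'   `session_log`s.
#' @param reports Optional data frame (`participant_id`,
#'   `report_category`) of externally supplied written-report categories;
#'   participants absent from it get `"not_available"`.
#' @param correct Continuity correction for the halves chi-square.
#' @return Data frame with one row per participant.
#' @export
cohort_table <- function(logs, reports = NULL, correct = TRUE) {
  if (inherits(logs, "cohort")) logs <- logs$logs
  if (length(logs) == 0L) stop("no session logs supplied")
  ids <- vapply(logs, function(l) l$participant_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate participant_id: ",
                               ids[duplicated(ids)][1])
  rows <- lapply(logs, function(l) {
    rc <- "not_available"
    if (!is.null(reports)) {
      hit <- reports$report_category[reports$participant_id == l$participant_id]
      if (length(hit) == 1L) rc <- hit
    }
    classify_participant(l, rc, correct = correct)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- "data.frame"
  out
}
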