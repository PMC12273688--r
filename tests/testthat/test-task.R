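test_that("generated sequences are balanced units of the three trial types", {
  s <- generate_sequence(167, seed = 1)
  expect_length(s, 501)
  expect_equal(unname(table(s)[c("AB", "CD", "EF")]), rep(167L, 3),
               ignore_attr = TRUE)
  # every consecutive block of 3 is a permutation of the three types
  for (u in seq_len(167)) {
    expect_setequal(s[(3 * u - 2):(3 * u)], c("AB", "CD", "EF"))
  }
  expect_equal(generate_sequence(1, seed = 2) |> sort(),
               c("AB", "CD", "EF"))
  expect_error(generate_sequence(0), "positive")
})

test_that("unit permutations are uniform across the six orderings", {
  s <- generate_sequence(6000, seed = 3)
  units <- apply(matrix(s, nrow = 3), 2, paste, collapse = "")
  counts <- table(units)
  expect_length(counts, 6)
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("no more than two CD trials separate consecutive EF trials", {
  # exhaustive: all 36 ordered pairs of adjacent unit orderings
  perms <- list(c("AB","CD","EF"), c("AB","EF","CD"), c("CD","AB","EF"),
                c("CD","EF","AB"), c("EF","AB","CD"), c("EF","CD","AB"))
  worst <- 0L
  for (p1 in perms) for (p2 in perms) {
    seqc <- c(p1, p2)
    ef_pos <- which(seqc == "EF")
    between <- sum(seqc[(ef_pos[1] + 1):(ef_pos[2] - 1)] == "CD")
    worst <- max(worst, between)
    expect_lte(between, 2L)
    expect_lte(max(pending_depth_profile(seqc)), 2L)
  }
  expect_equal(worst, 2L)  # the bound is attained
  # and by simulation on generated sequences
  depths <- vapply(1:500, function(i) {
    max(pending_depth_profile(generate_sequence(167, seed = i)))
  }, integer(1))
  expect_equal(max(depths), 2L)
})

test_that("pending depth profile matches hand traces", {
  expect_equal(pending_depth_profile(c("CD", "EF", "AB")), c(0L, 1L, 0L))
  # unit1 = EF,AB,CD; unit2 = CD,EF,AB reaches depth 2
  prof <- pending_depth_profile(c("EF", "AB", "CD", "CD", "EF", "AB"))
  expect_equal(prof, c(0L, 0L, 0L, 1L, 2L, 1L))
})

test_that("reward rules follow the immediate/delayed structure", {
  cfg <- session_config(n_units = 1, termination_enabled = FALSE)
  log <- run_session(policy_scripted(c("C", "F", "A")), cfg,
                     types = c("CD", "EF", "AB"))
  expect_equal(log$trials$rewarded, c(0L, 1L, 1L))
  expect_equal(log$trials$points_cum, c(0L, 1L, 2L))

  # always-D: every EF pays 0; total rewards = number of A choices
  cfg <- session_config(n_units = 30, seed = 5, termination_enabled = FALSE)
  log <- run_session(policy_always_second, cfg)
  expect_true(all(log$trials$rewarded[log$trials$pair == "EF"] == 0L))
  expect_equal(sum(log$trials$rewarded), 0L)
  logA <- run_session(policy_always_first, cfg)
  ef_rewards <- sum(logA$trials$rewarded[logA$trials$pair == "EF"])
  expect_true(all(logA$trials$rewarded[logA$trials$pair == "AB"] == 1L))
  expect_true(all(logA$trials$rewarded[logA$trials$pair == "CD"] == 0L))

  # an EF trial reached before any CD trial pays 0 even under always-C
  log <- run_session(policy_always_first,
                     session_config(n_units = 1, termination_enabled = FALSE),
                     types = c("EF", "AB", "CD"))
  expect_equal(log$trials$rewarded[1], 0L)
})

test_that("always-C conservation: EF rewards equal CD count minus at most one", {
  # The deficit equals the number of EF trials that found the queue empty.
  # The first unit ordering EF before CD always wastes its EF (the queue is
  # empty at unit boundaries until then); afterwards the queue carries a
  # permanent leftover, so no later EF is ever empty. Hence the deficit is
  # exactly 1 unless every unit orders CD before EF.
  for (seed in 1:40) {
    cfg <- session_config(n_units = 167, seed = seed,
                          termination_enabled = FALSE)
    log <- run_session(policy_always_first, cfg)
    tr <- log$trials
    ef_rewards <- sum(tr$rewarded[tr$pair == "EF"])
    n_cd <- sum(tr$pair == "CD")
    ef_before_cd <- vapply(seq_len(log$config$n_units), function(u) {
      unit <- tr$pair[tr$unit == u]
      which(unit == "EF") < which(unit == "CD")
    }, logical(1))
    deficit <- as.integer(any(ef_before_cd))
    expect_true(ef_rewards %in% c(n_cd - 1L, n_cd))
    expect_equal(ef_rewards, n_cd - deficit)
    # a last CD falling after the last EF always leaves its entry pending
    if (max(which(tr$pair == "CD")) > max(which(tr$pair == "EF")))
      expect_equal(ef_rewards, n_cd - 1L)
  }
})

test_that("a policy returning an out-of-pair role is rejected", {
  bad <- function(trial_type, history) "A"
  expect_error(
    run_session(bad, session_config(n_units = 1), types = c("CD", "AB", "EF")),
    "policy returned"
  )
})

test_that("termination fires at the CD trial completing the second qualifying bin", {
  cfg <- session_config(n_units = 167, seed = 11, termination_enabled = TRUE)
  log <- run_session(policy_always_first, cfg)  # always C
  expect_true(log$terminated_early)
  tr <- log$trials
  # the terminating trial is the 20th CD trial, and is the last presented
  cd_rows <- which(tr$pair == "CD")
  expect_length(cd_rows, 20)
  expect_equal(log$termination_trial, cd_rows[20])
  expect_equal(log$termination_trial, nrow(tr))
  # in-session detection agrees with the analysis-side detector
  crit <- detect_criterion(tr$choice[cd_rows], "C")
  expect_true(crit$met)
  expect_equal(crit$completing_trial, 20L)

  # disabled flag: same policy runs to full length
  cfg$termination_enabled <- FALSE
  full <- run_session(policy_always_first, cfg)
  expect_equal(nrow(full$trials), 501L)
  expect_false(full$terminated_early)
})

test_that("sessions are bitwise reproducible from their seed", {
  cfg <- session_config(n_units = 20, seed = 99, termination_enabled = FALSE)
  l1 <- run_session(policy_random, cfg)
  l2 <- run_session(policy_random, cfg)
  expect_identical(l1$trials, l2$trials)
})

test_that("lag distribution matches hand traces and stays within 1..5", {
  cfg1 <- session_config(n_units = 1, termination_enabled = FALSE)
  log <- run_session(policy_always_first, cfg1, types = c("CD", "EF", "AB"))
  expect_equal(lag_distribution(log), 1L)

  # unit1 = (EF, CD, AB), unit2 = (AB, CD, EF): only the first CD entry is
  # consumed, by the EF at trial 6 (FIFO), giving lag 4; the second stays
  # pending and is omitted
  cfg2 <- session_config(n_units = 2, termination_enabled = FALSE)
  log <- run_session(policy_always_first, cfg2,
                     types = c("EF", "CD", "AB", "AB", "CD", "EF"))
  expect_equal(lag_distribution(log), 4L)
  # with a third unit opening EF, the pending entry resolves at trial 7
  cfg3 <- session_config(n_units = 3, termination_enabled = FALSE)
  log <- run_session(policy_always_first, cfg3,
                     types = c("EF", "CD", "AB", "AB", "CD", "EF",
                               "EF", "AB", "CD"))
  expect_equal(lag_distribution(log), c(4L, 2L))

  lags <- unlist(lapply(1:50, function(i) {
    lag_distribution(run_session(
      policy_random,
      session_config(n_units = 167, seed = i, termination_enabled = FALSE)
    ))
  }))
  expect_true(all(lags %in% 1:5))
  expect_equal(mean(lags), 3, tolerance = 0.1)
})

test_that("session rewards match the brute-force history-scanning oracle", {
  for (seed in 1:60) {
    cfg <- session_config(n_units = sample(1:8, 1), seed = seed,
                          termination_enabled = FALSE)
    log <- run_session(policy_random, cfg)
    expect_equal(log$trials$rewarded,
                 oracle_rewards(log$trials$pair, log$trials$choice))
  }
})
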