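# Independent reference implementations used to cross-check the package.
# Each is deliberately naive (explicit scans / loops / closed forms) and
# shares no code with the functions it checks.

# Re-derive every reward by scanning the full history for the earliest
# CD choice not yet consumed by an earlier EF trial.
oracle_rewards <- function(pairs, choices) {
  n <- length(pairs)
  r <- integer(n)
  consumed <- logical(n)
  for (i in seq_len(n)) {
    if (pairs[i] == "AB") {
      r[i] <- as.integer(choices[i] == "A")
    } else if (pairs[i] == "EF") {
      j <- which(pairs == "CD" & !consumed & seq_len(n) < i)
      if (length(j) > 0L) {
        j <- j[1L]
        consumed[j] <- TRUE
        r[i] <- as.integer(choices[j] == "C")
      }
    }
  }
  r
}

# Enumerate every window of n_consecutive full bins; return the same-pair
# trial ordinal completing the first qualifying window, or NA.
oracle_criterion_trial <- function(ind, bin_size = 10L, threshold = 8L,
                                   n_consecutive = 2L) {
  n_bins <- length(ind) %/% bin_size
  if (n_bins >= n_consecutive) {
    for (b in n_consecutive:n_bins) {
      ok <- vapply((b - n_consecutive + 1L):b, function(bb) {
        sum(ind[((bb - 1L) * bin_size + 1L):(bb * bin_size)]) >= threshold
      }, logical(1))
      if (all(ok)) return(b * bin_size)
    }
  }
  NA_integer_
}

# Two-sided exact binomial p against 0.5 by direct point-probability
# summation over all n + 1 outcomes.
oracle_binom_p <- function(x, n) {
  d <- stats::dbinom(0:n, n, 0.5)
  min(1, sum(d[d <= d[x + 1L] * (1 + 1e-7)]))
}

# Two-sided Fisher exact p by hypergeometric enumeration with choose().
oracle_fisher_p <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  obs <- choose(r1, m[1, 1]) * choose(r2, c1 - m[1, 1]) / choose(n, c1)
  min(1, sum(pk[pk <= obs * (1 + 1e-7)]))
}

# 2x2 chi-square with continuity correction from the textbook formula.
oracle_chisq2x2 <- function(m, correct = TRUE) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  adj <- if (correct) pmin(0.5, abs(m - e)) else 0
  stat <- sum((abs(m - e) - adj)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Straight-line single agent step: explicit loops over the six roles and
# three states, no vectorization.
oracle_agent_step <- function(q, eta, v, trial_type, next_trial_type,
                              choice, r, params) {
  roles <- c("A", "B", "C", "D", "E", "F")
  states <- c("AB", "CD", "EF")
  for (x in roles) eta[[x]] <- params$lam * eta[[x]]
  eta[[choice]] <- eta[[choice]] + 1
  if (params$algorithm == "actor_critic") {
    vn <- 0
    if (!is.null(next_trial_type)) vn <- v[[next_trial_type]]
    delta <- r + params$gamma * vn - v[[trial_type]]
  } else {
    qn <- 0
    if (!is.null(next_trial_type)) {
      p <- pair_roles(next_trial_type)
      qn <- q[[p[1]]]
      if (q[[p[2]]] > qn) qn <- q[[p[2]]]
    }
    delta <- r + params$gamma * qn - q[[choice]]
  }
  for (x in roles) q[[x]] <- q[[x]] + params$alpha * eta[[x]] * delta
  for (s in states) {
    p <- pair_roles(s)
    v[[s]] <- v[[s]] + params$alpha * (eta[[p[1]]] + eta[[p[2]]]) * delta
  }
  list(q = q, eta = eta, v = v, delta = delta)
}

# Scripted policies used throughout the tests.
policy_always_first <- function(trial_type, history) pair_roles(trial_type)[1]
policy_always_second <- function(trial_type, history) pair_roles(trial_type)[2]
policy_random <- function(trial_type, history) sample(pair_roles(trial_type), 1)

# Policy choosing the first option for each type's trials 1..switch_at and
# the second option afterwards (per-type ordinal, not global trial index).
policy_per_type_switch <- function(switch_at) {
  seen <- c(AB = 0L, CD = 0L, EF = 0L)
  function(trial_type, history) {
    seen[trial_type] <<- seen[trial_type] + 1L
    pair_roles(trial_type)[if (seen[trial_type] <= switch_at) 1L else 2L]
  }
}

# Policy replaying a fixed choice vector, one entry per trial.
policy_scripted <- function(choices) {
  i <- 0L
  function(trial_type, history) {
    i <<- i + 1L
    choices[i]
  }
}
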