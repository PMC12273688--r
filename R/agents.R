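#' Agent parameters
#'
#' Parameters of the softmax eligibility-trace learners: learning rate
#' `alpha`, inverse temperature `beta` (0 = fully random choice), trace
#' scale `lam` (how far back credit from a reward prediction error
#' propagates), and discount factor `gamma`.
#'
#' @param algorithm `"actor_critic"` (separate state values drive the
#'   prediction error) or `"q_learning"` (the next pair's maximum action
#'   value drives it).
#' @param alpha Learning rate in (0, 1].
#' @param beta Inverse temperature, >= 0.
#' @param lam Trace decay scale in \[0, 1\].
#' @param gamma Discount factor in \[0, 1\].
#' @param preset Optional preset label carried along in metadata.
#' @return An object of class `agent_params`.
#' @seealso [agent_preset()] for the four named presets.
#' @export
agent_params <- function(algorithm = c("actor_critic", "q_learning"),
                         alpha, beta, lam, gamma = 0.5, preset = "custom") {
  algorithm <- match.arg(algorithm)
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0, 1]")
  if (beta < 0) stop("beta must be non-negative")
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  structure(
    list(algorithm = algorithm, alpha = alpha, beta = beta,
         lam = lam, gamma = gamma, preset = preset),
    class = "agent_params"
  )
}

## the four canonical parameter regimes; gamma = 0.5 throughout
.PRESETS <- list(
  slow_learning    = list(alpha = 0.001, beta = 4,    lam = 0.5),
  high_exploration = list(alpha = 0.1,   beta = 0.01, lam = 0.5),
  short_trace      = list(alpha = 0.1,   beta = 4,    lam = 0.01),
  long_trace       = list(alpha = 0.1,   beta = 4,    lam = 0.5)
)

#' Named parameter presets
#'
#' Resolves one of the four canonical parameter regimes:
#' `slow_learning` (alpha 0.001, beta 4, lambda 0.5),
#' `high_exploration` (alpha 0.1, beta 0.01, lambda 0.5),
#' `short_trace` (alpha 0.1, beta 4, lambda 0.01),
#' `long_trace` (alpha 0.1, beta 4, lambda 0.5); gamma is 0.5 for all.
#' Only the long-trace regime learns to choose the delayed-reward stimulus;
#' the short trace learns only the immediately rewarded one.
#'
#' @param name Preset name.
#' @param algorithm `"actor_critic"` or `"q_learning"`.
#' @return An `agent_params` object.
#' @export
#' @examples
#' agent_preset("long_trace", "q_learning")
agent_preset <- function(name = c("slow_learning", "high_exploration",
                                  "short_trace", "long_trace"),
                         algorithm = c("actor_critic", "q_learning")) {
  name <- match.arg(name)
  algorithm <- match.arg(algorithm)
  p <- .PRESETS[[name]]
  agent_params(algorithm, alpha = p$alpha, beta = p$beta, lam = p$lam,
               gamma = 0.5, preset = name)
}

#' Initial agent state
#'
#' Policy parameters `q` (one per stimulus role), eligibility traces `eta`
#' (one per role) and state values `v` (one per trial type), all starting
#' at exactly 0.
#'
#' @return An object of class `agent_state`.
#' @export
agent_state <- function() {
  structure(
    list(
      q   = stats::setNames(numeric(6), ROLES),
      eta = stats::setNames(numeric(6), ROLES),
      v   = stats::setNames(numeric(3), TRIAL_TYPES)
    ),
    class = "agent_state"
  )
}

#' Softmax probability of choosing the first option
#'
#' `(1 + exp(beta * (q_second - q_first)))^-1`, computed in a saturating
#' form so large `beta * dq` cannot overflow. `beta = 0` gives 0.5
#' regardless of the values.
#'
#' @param q_first,q_second Policy parameters of the two options.
#' @param beta Inverse temperature, >= 0.
#' @return Probability in (0, 1); `prob(x, y, b) + prob(y, x, b) == 1`.
#' @export
#' @examples
#' softmax_prob(1, 0, 4)   # 1 / (1 + exp(-4))
softmax_prob <- function(q_first, q_second, beta) {
  stats::plogis(beta * (q_first - q_second))
}

#' Decay and increment eligibility traces
#'
#' Every role's trace is multiplied by `lam`; the chosen role's trace is
#' then incremented by 1. Traces of roles not presented this trial decay
#' too, which is what lets a later prediction error reach past choices.
#'
#' @param state An `agent_state`.
#' @param chosen The role chosen this trial.
#' @param lam Trace decay in \[0, 1\].
#' @return The updated `agent_state`.
#' @export
update_traces <- function(state, chosen, lam) {
  state$eta <- state$eta * lam
  state$eta[[chosen]] <- state$eta[[chosen]] + 1
  state
}

#' Actor-critic reward prediction error
#'
#' `delta = r + gamma * v_next - v_current`, where the `v`s are the values
#' of the current and upcoming trial types (states).
#'
#' @param r Reward (0/1) received this trial.
#' @param v_current,v_next State values before any update this step;
#'   `v_next` is 0 at the final trial (episodic terminal convention).
#' @param gamma Discount factor.
#' @return The prediction error `delta`.
#' @export
rpe_actor_critic <- function(r, v_current, v_next, gamma) {
  r + gamma * v_next - v_current
}

#' Q-learning reward prediction error
#'
#' `delta = r + gamma * max_q_next - q_chosen`, where `max_q_next` is the
#' larger of the two policy parameters of the next trial's pair, evaluated
#' before any update this step (0 at the final trial).
#'
#' @param r Reward (0/1) received this trial.
#' @param q_chosen Pre-update policy parameter of the chosen role.
#' @param q_next_max Pre-update maximum over the next pair's parameters.
#' @param gamma Discount factor.
#' @return The prediction error `delta`.
#' @export
rpe_q_learning <- function(r, q_chosen, q_next_max, gamma) {
  r + gamma * q_next_max - q_chosen
}

#' Apply the trace-weighted updates
#'
#' Every policy parameter moves by `alpha * eta_X * delta`; every state
#' value (all three trial types, every step) moves by
#' `alpha * (eta_X + eta_Y) * delta` where X, Y are the state's pair.
#' States not currently presented move only through their decayed traces.
#'
#' @param state An `agent_state` whose traces are already updated for this
#'   step.
#' @param delta Reward prediction error.
#' @param alpha Learning rate.
#' @return The updated `agent_state`.
#' @export
apply_updates <- function(state, delta, alpha) {
  state$q <- state$q + alpha * state$eta * delta
  pair_eta <- state$eta[c(1L, 3L, 5L)] + state$eta[c(2L, 4L, 6L)]
  state$v <- state$v + alpha * as.vector(pair_eta) * delta
  state
}

#' One full agent step
#'
#' Orchestrates a single trial in the stated order: choose by softmax over
#' the presented pair, observe the reward, decay/increment traces, compute
#' the prediction error from pre-update values (actor-critic from state
#' values, Q-learning from the chosen and next-pair action values), then
#' apply the `q` and `v` updates.
#'
#' @param state An `agent_state`.
#' @param trial_type The presented trial type.
#' @param next_trial_type The upcoming trial type, or `NULL` at the final
#'   trial (next-state terms are then 0).
#' @param params An `agent_params`.
#' @param reward_fn Environment callback `(trial_type, choice) -> 0/1`.
#' @param choice Optional forced choice (bypasses the softmax draw).
#' @return List with `choice`, `reward`, `delta` and the updated `state`.
#' @export
agent_step <- function(state, trial_type, next_trial_type, params,
                       reward_fn, choice = NULL) {
  pair <- pair_roles(trial_type)
  if (is.null(choice)) {
    p_first <- softmax_prob(state$q[[pair[1L]]], state$q[[pair[2L]]],
                            params$beta)
    choice <- if (stats::runif(1) < p_first) pair[1L] else pair[2L]
  } else if (!choice %in% pair) {
    stop("choice '", choice, "' not in pair ", trial_type)
  }
  r <- reward_fn(trial_type, choice)
  state <- update_traces(state, choice, params$lam)
  delta <- if (params$algorithm == "actor_critic") {
    v_next <- if (is.null(next_trial_type)) 0 else state$v[[next_trial_type]]
    rpe_actor_critic(r, state$v[[trial_type]], v_next, params$gamma)
  } else {
    q_next_max <- if (is.null(next_trial_type)) 0 else
      max(state$q[pair_roles(next_trial_type)])
    rpe_q_learning(r, state$q[[choice]], q_next_max, params$gamma)
  }
  state <- apply_updates(state, delta, params$alpha)
  list(choice = choice, reward = r, delta = delta, state = state)
}

#' Stateful choice policy wrapping an eligibility-trace learner
#'
#' Returns a policy closure usable with [run_session()]. Because the
#' environment reveals a trial's reward only after the choice, the learning
#' update for trial `t` is applied when trial `t + 1` is presented — at
#' which point the upcoming state needed by the prediction error is known.
#' The update for the session's final trial is never applied; it cannot
#' influence any recorded choice.
#'
#' @param params An `agent_params`.
#' @return A function `(trial_type, history) -> role` with internal state.
#' @export
#' @examples
#' pol <- agent_policy(agent_preset("long_trace"))
#' log <- run_session(pol, session_config(n_units = 10, seed = 1,
#'                                        termination_enabled = FALSE))
agent_policy <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  st <- agent_state()
  prev_type <- NULL
  prev_choice <- NULL
  function(trial_type, history) {
    if (!is.null(prev_type)) {
      r <- history$rewarded[history$n]
      st <<- update_traces(st, prev_choice, params$lam)
      delta <- if (params$algorithm == "actor_critic") {
        rpe_actor_critic(r, st$v[[prev_type]], st$v[[trial_type]],
                         params$gamma)
      } else {
        rpe_q_learning(r, st$q[[prev_choice]],
                       max(st$q[pair_roles(trial_type)]), params$gamma)
      }
      st <<- apply_updates(st, delta, params$alpha)
    }
    pair <- pair_roles(trial_type)
    p_first <- softmax_prob(st$q[[pair[1L]]], st$q[[pair[2L]]], params$beta)
    ch <- if (stats::runif(1) < p_first) pair[1L] else pair[2L]
    prev_type <<- trial_type
    prev_choice <<- ch
    ch
  }
}

#' Run a learning agent through one session
#'
#' Convenience wrapper: builds an [agent_policy()] and runs it with
#' [run_session()]. Simulation sessions conventionally run without the
#' early-termination criterion (fixed-length sessions); pass a config with
#' `termination_enabled = TRUE` to enable it.
#'
#' @param params An `agent_params`.
#' @param config A [session_config()]; default 160 units (480 trials),
#'   no early termination.
#' @param participant_id Label stored in the log.
#' @return A `session_log` whose `agent_meta` records algorithm, preset and
#'   seed.
#' @export
run_agent_session <- function(params,
                              config = session_config(
                                n_units = 160L, termination_enabled = FALSE
                              ),
                              participant_id = "agent") {
  meta <- sprintf("algorithm=%s preset=%s seed=%s", params$algorithm,
                  params$preset,
                  if (is.null(config$seed)) "NA" else config$seed)
  run_session(agent_policy(params), config,
              participant_id = participant_id, agent_meta = meta)
}
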