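---
title: "Modelling delayed, state-transition-free feedback: task, agents and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling delayed, state-transition-free feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delaycredit)
```

## The scientific problem

When the outcome of a choice arrives only after several unrelated
intervening choices, a learner faces the temporal credit assignment
problem: which past action caused the reward now on the screen? Most
laboratory tasks sidestep it — feedback follows the causal action
immediately, or after a fixed, announced delay. This package implements
a task in which the delay is variable (one to five trials), unannounced,
and — crucially — *state-transition-free*: the sequence of upcoming
trial types is independent of the learner's choices, so models that
learn step-by-step transition structure gain nothing. Under these
conditions, credit can only be carried by a memory of recent actions,
which is exactly what eligibility-trace reinforcement learning
formalizes.

## Task mechanics and design choices

Each session interleaves three two-choice pairs. AB trials reward A
immediately. CD trials never reward immediately but enqueue the choice
(C = will pay, D = will not) on a FIFO queue. Each EF trial dequeues the
oldest entry and pays it out; E and F themselves are causally inert.
Trials come in units of three — one trial of each pair, order drawn
uniformly over the six permutations, independently across units. Two
structural consequences follow, both proven by enumeration of adjacent
unit orderings and property-tested on generated sequences:

* at most **two** CD outcomes are ever pending (queue depth ≤ 2);
* the choice-to-outcome lag lies in **1–5 trials** with mean ≈ 3.

A session has 167 units (501 trials; 16 full 10-trial bins per pair type
plus a trailing 7-trial bin, which is excluded from bin-based
statistics). With the termination criterion enabled, the session ends at
the CD trial completing the second consecutive 10-trial CD bin with ≥ 8
C choices — immediately, with no further trials of the current unit
presented, since the criterion exists to catch the learner right after
the bias forms. Bins are non-overlapping and counted from the session
start, so the criterion can first fire at CD trial 20.

Points of genuine design freedom, and what this package does:

* **EF with an empty queue** (possible whenever the queue has drained
  and a unit opens with EF) pays 0 — there is simply no pending outcome.
  A consequence worth knowing: in an always-C session the total of EF
  rewards is the CD count minus one in essentially every session,
  because the *first* unit that orders EF before CD wastes that EF on an
  empty queue, after which the queue permanently carries one leftover
  entry. The deficit is therefore a property of unit orderings anywhere
  in the session, not of how the session happens to end.
* **One random stream per session**, seeded from the session config and
  consumed in trial order (sequence first, then one draw per trial), so
  every log is bitwise reproducible from its seed.
* Screen geometry, stimulus images and reaction times are not modelled;
  they affect no computed quantity.

## The agents

Choices are softmax in the policy parameters of the presented pair,
$P\{a=X\} = (1+e^{\beta(q_Y - q_X)})^{-1}$ (computed via a saturating
logistic, so extreme $\beta \Delta q$ cannot overflow). All six traces
decay every trial, $\eta_X \leftarrow \lambda \eta_X$, and the chosen
role's trace gains 1; for $\lambda < 1$ this bounds every trace by
$1/(1-\lambda)$. The prediction error uses *pre-update* values:
actor-critic takes $\delta = r + \gamma v_{s'} - v_s$ from the state
values of the current and upcoming pair; Q-learning takes
$\delta = r + \gamma \max q_{\text{next pair}} - q_{\text{chosen}}$.
Then every $q_X$ moves by $\alpha \eta_X \delta$ and every state value —
all three, every trial — by $\alpha(\eta_X + \eta_Y)\delta$ over its
pair's traces. At the final trial the next-state term is taken as 0
(standard episodic convention; over 480-trial sessions the choice made
there is the last one, so the convention cannot affect any recorded
behavior).

Because the environment reveals a trial's reward only after the choice,
the stateful policy applies trial $t$'s update when trial $t+1$ is
presented — at which point the upcoming state is known. A test verifies
this deferred scheme is trial-for-trial identical to stepping the
explicit `agent_step()` over a pre-generated sequence.

Parameters (all dimensionless): learning rate $\alpha \in (0,1]$,
inverse temperature $\beta \ge 0$ ($\beta = 0$ is a fair coin), trace
scale $\lambda \in [0,1]$, discount $\gamma \in [0,1]$. The four presets
(γ = 0.5 throughout) span the regimes of interest: *slow learning*
(0.001, 4, 0.5), *high exploration* (0.1, 0.01, 0.5), *short trace*
(0.1, 4, 0.01), *long trace* (0.1, 4, 0.5). The standard grid runs each
algorithm × preset cell 200 times for 480 trials (160 units, 16 bins),
termination disabled.

```{r grid, eval = FALSE}
summaries <- run_grid(grid_spec(master_seed = 1))
aggregate(cbind(count_A, count_C, count_E) ~ algorithm + preset,
          summaries, mean)
```

The qualitative pattern is sharp: the long trace lifts both A and C to
near-ceiling; the short trace lifts A only; slow learning and high
exploration lift nothing much. Two second-order effects of the printed
equations are worth stating because they are real model behavior, not
noise: at $\alpha = 0.001$, 480 trials of immediate reward still
accumulate $q_A - q_B \approx 0.1$, which $\beta = 4$ converts into a
final-bin A rate near 0.58 — a visible drift above chance; and under the
actor-critic short trace, lag-1 deliveries (a CD immediately followed by
its paying EF) leave $\eta_C = \lambda$ at the rewarded step, giving C a
small but systematic credit (final-bin C ≈ 5.3–5.5/10). Strict
"at chance" readings of those regimes fail at high statistical power
even though the regimes clearly do not *learn* the contingencies.

## The synthetic cohort

Human cohorts on this task are strikingly heterogeneous. The generator
emulates that heterogeneity with scripted archetypes — independent
Bernoulli choosers parameterized per pair: `c_learner` (A at 0.95, C
stepping 0.5 → 0.95 after the 30th CD trial, emulating mid-session
discovery so the halves chi-square has a true positive to detect),
`d_perseverator` (C at 0.15), `e_superstitious`/`f_superstitious` (E at
0.9 / 0.1), `random_chooser` (all 0.5) and `immediate_only` (A at 0.95,
everything else 0.5). The probabilities are artifact parameters chosen
for statistical power at 167 CD trials — e.g.
$P(\mathrm{Bin}(10, 0.95) \ge 8)^2 \approx 0.977$ per bin pair, so a
ramped learner almost always terminates — **not** measurements of any
human cohort. What passing label-recovery tests show is that the
pipeline detects the patterns it was built to detect at realistic
session lengths; they say nothing about how often such patterns occur in
people, nor do the archetypes capture richer human features
(autocorrelated choices, drifting attention, within-session strategy
switches beyond one step, reaction times).

Per-participant seeds are derived from the master seed by a counter
scheme, so growing a cohort never reshuffles existing participants'
streams.

## The analysis pipeline

End-of-session choice rates are exponentially weighted means over the
last 30 trials *of each pair type* (weights $0.9^\tau$, normalized;
windows within a type, since interleaving other pairs into the window
would cap observable rates at ⅓). Sessions shorter than the window
renormalize over what exists. The six classification criteria per
participant: C criterion, D criterion (same bins, target D), overall
C-vs-D exact binomial, first-vs-second-half 2×2 chi-square with
direction, overall E-vs-F exact binomial, and Fisher's exact test of
whether delayed rewards happened to follow one of E/F more often
(apparent immediate reward — the suspected driver of superstitious
bias). All tests are two-tailed at α = 0.05 with no multiplicity
adjustment, deliberately: the analysis characterizes individuals, and
flags are meant to be read per cell, not as family-wise discoveries.

Numerical conventions, surfaced as arguments with these defaults: the
two-sided binomial p sums all outcomes with point probability at most
that of the observed count; the chi-square uses the continuity
correction (`correct = FALSE` disables it); the halves split divides the
CD trials of that type at ⌈n/2⌉ by presentation order (trial types are
balanced, so this nearly coincides with the global-index split while
keeping the 2×2 margins clean); a participant who chose only C (or only
D) makes the halves table degenerate — the test returns p = 1 with a
flag rather than an error. Every test is checked against an independent
exact-enumeration oracle (all binomial inputs to n = 200; all 2×2
tables to total 24 plus random larger margins).

## Problem sizes and determinism

The shipped checks use 10,000 generated sequences for the queue bound,
1000 sessions (166,000 delivered outcomes) for the lag statistics, the
full 1600-session grid for the regime contrasts, and 500 labelled
sessions for recovery and false-positive calibration — sizes at which
every binomial band used is narrow relative to the effects, while a full
run stays in the minutes range on a single core. All stochastic entry
points take explicit seeds; repeated runs are bitwise identical.

## Known limitations

* Archetypes are stylized; no attempt is made to fit them to human data,
  and written-report categories are consumed as external labels only.
* No model fitting, likelihoods or model comparison for the RL agents —
  the simulation answers feasibility ("can this model class learn the
  task?"), not inference about what any participant actually did.
* The D-perseveration pattern observed in humans is *not* explicable by
  these model-free agents (D is never reinforced); the archetype
  reproduces the behavior, not a mechanism.
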