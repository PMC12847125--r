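---
title: "An optimal finite-horizon agent for a timed patch-foraging task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An optimal finite-horizon agent for a timed patch-foraging task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchforage)
```

## The task

A forager has a fixed time budget (a "battery": 50 s in the long condition,
25 s in the short one) to harvest coins from four areas, each holding five
boxes. Boxes deplete linearly in collection order: a rich area pays
8, 7, 6, 5, 4 coins, a poor one 5, 4, 3, 2, 1. The environment is either
*rich* (all four areas rich) or *mixed* (exactly two rich and two poor,
placed uniformly at random among the six possible layouts). The forager
always knows the environment label — a sensor announces it at trial start —
but in a mixed environment it does not know *which* areas are rich; an
area's type is revealed by collecting its first box.

Two timing parameters abstract all navigation: collecting the next box
within the current area takes $T_1$ seconds, and leaving, travelling to
another area, and collecting its first box takes $T_2 > T_1$ seconds. The
reference values are the population means $T_1 = 3.41$ s and $T_2 = 6.10$ s.
Because the horizon is fixed and short, the classical marginal value theorem
(which assumes rate maximization over an unbounded horizon) does not apply;
the reward-maximizing policy must instead be computed for the finite budget.

## The optimal agent

The decision problem is a finite-horizon stochastic decision tree. A state
is the triple (time remaining, knowledge state, current location). The
knowledge state records, per area, either the revealed richness with the
number of boxes already taken, or "unknown"; we mirror the compact tuple
notation in which `(7, 4, ?, ?)` means the next box in area 1 pays 7 coins,
the next in area 2 pays 4, and areas 3 and 4 are unexplored.

Two action families exist: *stay* (collect the next box here, cost $T_1$)
and *move* (travel to another area and collect a box there, cost $T_2$).
An action is feasible only when its target still has boxes and its full
cost fits in the remaining time; the trial ends when nothing is feasible.
Values are expected coins-to-go with terminal value zero,

$$ V(s) = \max_{a \in \mathcal A(s)} \; \mathbb E\!\left[ r(s,a) + V(s') \right], $$

where the expectation is non-trivial only when the move target is
unexplored: the first box then reveals the area's type, rich with
probability

$$ p(\text{rich}) = \frac{2 - n_\text{rich revealed}}{4 - n_\text{revealed}}, $$

the posterior of the two-rich/two-poor urn. Beliefs are exact, never
sampled: only six layouts exist, and the package carries the joint
(anti-correlated) structure through `consistent_configs()`, the enumerated
posterior support. Forced inferences are applied after every reveal — once
two areas of one type are known, the others are known too
(`apply_closure()`) — and `uncertainty_resolved()` flags the moment the full
layout becomes inferable, the quantity used in the switch-probability
analysis.

`optimal_forager()` solves one condition (environment label x battery) for
one pair of timing parameters by memoized backward induction; the recursion
is implemented in C++ because the cohort simulator queries it tens of
thousands of times. Memo keys quantize the remaining time at $10^{-6}$ s
for hashing only; all values are computed in double precision. With two
action costs the reachable times form the small lattice
$\{B - i\,T_1 - j\,T_2\}$, so trees stay compact.

### Numerical choices

* **First action.** The forager starts in a central zone where time does
  not deplete. Entering the first area and collecting its first box is
  charged $T_1$ (the accounting used by the reference decision tree); the
  `first_move` argument switches this to $T_2$ for sensitivity checks.
* **Feasibility at the buzzer.** An action must fit entirely in the
  remaining time (comparisons use a $10^{-9}$ s guard against floating
  accumulation). There are no partial collections.
* **Value convention.** Coins-to-go with terminal value zero, rather than
  cumulative coins at the leaves; the two are equivalent for the argmax, and
  a unit test confirms the root value equals the realized coins along the
  deterministic rich-environment path.
* **Tie-breaking.** Staying beats moving; among moves the lowest area index
  wins. Ties are generic at symmetric states (e.g. the four unexplored
  areas at the root), and the fixed rule makes every optimal trajectory,
  log and test deterministic. One consequence worth knowing: the optimal
  agent always enters area 1 first.
* **Revisits** are allowed whenever boxes remain, as in the task.

Two behavioral signatures summarize the solution at the reference timing:
in a mixed environment the optimal agent takes *extreme* patch-leaving
decisions, exhausting all five boxes of the first area when it is rich and
the battery long, but taking exactly one box and leaving when it is poor
and the battery short. And in a rich environment the tree contains no
stochastic node, so there is a single optimal path: every rollout statistic
is an integer-valued point mass (84 coins in 50 s, 42 in 25 s).

## Rollouts and the synthetic cohort

`run_trial()` walks any policy through a hidden layout, producing an event
log (timestamps, areas, box ordinals, coins) whose invariants are checked
by `validate_trial_log()`. For the optimal policy the only randomness is
the layout itself, so `exact_statistics()` computes expectations by direct
enumeration of the six layouts, and `rollout_statistics()` provides the
Monte-Carlo counterpart (the reference analysis used $10^5$ trajectories
per subject and condition; tests use $10^3$–$10^4$ with correspondingly
widened tolerances).

Human data for this task are not redistributable, so the analysis stage is
exercised end-to-end on a synthetic cohort (`simulate_cohort()`) that
reproduces the study design: 34 subjects, two battery blocks of 20 trials
(block order counterbalanced 17/17), each trial independently rich or
mixed. Deviations from optimality are modelled minimally:

* **Timing variability.** Per-subject $T_1, T_2$ are drawn from truncated
  normals with the population moments $3.41 \pm 0.53$ s and
  $6.10 \pm 0.72$ s, constrained to $T_2 > T_1 > 0.5$ s. Within a trial,
  each action's realized duration gets truncated-normal jitter
  (`jitter_sd`, default 0.3 s — chosen once as a plausible execution
  variability of the same order as the between-subject spread; the floor is
  0.5 s and the cap is the remaining battery, so logs never overrun the
  budget). Agents plan with their nominal parameters.
* **Decision noise.** `noisy_policy()` softmaxes the solver's action
  values: $P(a) \propto \exp(Q(a)/\beta)$. $\beta = 0$ reproduces the
  optimal policy exactly; the default $\beta = 1$ coin produces clearly
  sub-optimal but purposeful behavior (errors concentrate where action
  values are close, which is where humans are variable too).
* **Learning modifiers**, both off by default: a per-trial multiplicative
  speed-up of the timing parameters and a per-trial decay of $\beta$. They
  exist to give the trend-fitting machinery a known positive case.

The rich/mixed assignment is a fair coin per trial because the true
proportions used in the study are not published; `prop_mixed` overrides it.

What the generator does *not* emulate: spatial navigation and box search
within areas (abstracted into $T_1/T_2$, exactly as the optimal model
abstracts them), memory limits, systematic biases such as fixed
leave-after-$k$ rules, and any learning of task statistics beyond the two
modifiers. Passing tests therefore validate the pipeline's correctness on
design-matched data, not cognitive fidelity to human foragers.

## The analysis stage

`summarize_trials()` computes the six dependent variables per trial: total
coins; boxes collected in the first area; boxes collected; average coins
per box; number of unique areas visited; and average box collection time
(mean interval between consecutive same-area collections, missing when no
such interval exists — those trials are dropped from that variable's
analyses only). "First area" is anchored to the first collection event,
and *boxes in the first area* counts the initial contiguous run of
collections there: the patch-residence reading of the variable. (For the
optimal agent the two readings coincide, because the stay-preferring
tie-break makes its first-area exploitation contiguous.) First-area
richness is the area's true type, known post hoc from the hidden layout.

`estimate_timing()` recovers $T_1$ as the mean within-area
inter-collection interval and $T_2$ as the mean across-area interval,
pooling all of a subject's trials regardless of condition. On a noise-free
cohort the recovery is exact; under jitter it is consistent, with the
caveat that intervals capped at the buzzer introduce a negligible downward
bias. Consecutive same-area pairs that arise from a re-entry into a
previously visited area are treated as within-area intervals.

`switch_probability_table()` tabulates, per box ordinal, the probability of
leaving the current area, classified by environment label, the current
area's revealed richness, and whether the layout was already inferable at
that moment — five feasible condition cells, since a rich environment is
always resolved. The final collection of a trial is censored (excluded):
with the battery exhausted, staying was not an available choice, and
counting it as either decision would conflate time-outs with preferences.

`compare_to_optimal()` contrasts agent and optimal-agent summaries per
condition cell with two-sided Mann-Whitney tests (exact for small tie-free
samples, normal approximation with tie correction otherwise — the
`wilcox.test()` conventions, stated here so p-values are reproducible), and
`learning_trend()` fits an OLS line to per-trial-index means, the
learning-curve summary. Linear mixed models over subjects are deliberately
out of scope: the per-trial tables are tidy inputs for any mixed-model
package the analyst prefers.

## Problem sizes and limitations

The test suite solves full 50-s trees in milliseconds (they hold on the
order of $10^4$–$10^5$ memoized states); the brute-force cross-check
enumerates trees up to four actions deep, where exhaustive enumeration is
cheap and exact agreement to $10^{-9}$ is asserted over 200 randomized
timing/condition draws. Cohort-level checks run the full 34-subject design
once and smaller designs elsewhere; Monte-Carlo assertions use
$10^3$–$10^4$ trajectories with three-standard-error bands.

Known limitations: the belief machinery is specific to the four-area,
two-rich/two-poor composition (schedules and battery durations are
configurable, the composition is not); the noisy cohort is a pipeline
exercise, not a fitted model of human behavior, and none of its parameters
($\beta$, jitter, learning modifiers) are calibrated to participants; and
the package does not attempt the participant-side regression coefficients,
which require the original human dataset.
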