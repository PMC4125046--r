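---
title: "Collective learning and consensus decisions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective learning and consensus decisions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collectivelearning)
```

## The decision problem

A group of `n` individuals repeatedly chooses between two options, A and B.
On each trial one option is superior (uniformly at random), and two
environmental cues each point at one option:

* the **high-correlation cue** produces a *single shared signal* per trial —
  every group member sees the same draw, which is correct with probability
  `r_high`;
* the **low-correlation cue** produces *independent signals*, one per
  individual, each correct with probability `r_low`.

Both reliabilities live in `[0.5, 1]`. The distinction matters only in
groups: independent errors can be averaged away by vote aggregation, shared
errors cannot. When a shared signal is wrong, it is wrong for everyone.

Each individual casts a vote. When its two signals agree it votes for that
option; under conflict it follows the low-correlation cue with probability
`p` (its *voting behavior*). The group adopts the option with a majority of
votes, resolving ties uniformly at random, and every member experiences the
shared binary outcome: 1 if the chosen option was superior, 0 otherwise.

## Exact accuracy of a voting behavior

Condition on whether the shared signal is correct. Given that, voters are
independent with competence

$$q_1 = 1 - (1 - r_L)\,p \qquad q_0 = r_L\, p,$$

so the collective accuracy under simple majority is

$$A(p) = r_H\, M_n(q_1) + (1 - r_H)\, M_n(q_0),$$

where $M_n(q)$ is the Condorcet majority probability (binomial tail plus
half the tie mass for even $n$). `collective_accuracy()` implements this;
`majority_prob()` evaluates $M_n$ from `pbinom()`, whose tail computation is
numerically stable across the group sizes used here (hundreds); a
heterogeneous-competence version uses an exact $O(n^2)$ Poisson-binomial
dynamic program (`majority_prob_hetero()`).

Two identities anchor the landscape: $A(0) = r_H$ for every $n$ (a shared
signal gains nothing from grouping) and $A(1) = M_n(r_L)$ (classic Condorcet
improvement with group size). `optimal_policy()` maximizes $A$ over $p$ by a
coarse grid (step $10^{-3}$) with local refinement (`optimize()`, final
bracket $\le 10^{-6}$), snapping to a boundary when it is at least as good;
for odd $n$ an interior optimum satisfies the stationarity condition
$r_H (1-r_L) [q_1(1-q_1)]^{(n-1)/2} = (1-r_H)\, r_L\, [q_0(1-q_0)]^{(n-1)/2}$,
which the test suite uses as an independent verification of the optimizer,
never as the primary method. Three regimes result: exclusive reliance on the
low-correlation cue ($p^\*=1$, the common case in groups), exclusive
reliance on the high-correlation cue ($p^\*=0$, only when it is extremely
reliable), and a mixed strategy in between.

```{r landscape}
optimal_policy(25, env_config(r_low = 0.7, r_high = 0.8))
```

## Benchmarks

`global_optimal_accuracy()` compares three exact quantities: the best simple
majority can do with optimized `p`; the best over both `p` and an integer
supermajority threshold `m` with random deadlock resolution; and the
full-information Bayes bound obtained by weighting every raw signal by its
log-odds $\ln(r/(1-r))$ (Nitzan–Paroush aggregation). The ordering
restricted $\le$ global $\le$ Bayes is guaranteed by construction (the
threshold family contains simple majority; no rule beats the Bayes rule).
Ties and deadlocks contribute accuracy $\tfrac12$ everywhere, consistent
with random resolution. The supermajority family is the benchmark because a
submajority threshold with majority fallback can never improve on majority
rule for a symmetric binary choice; `threshold_decide()` still implements
submajority semantics (unique qualifier wins, double qualification falls
back to majority, no qualification randomizes) for completeness.

## The learning rule

Each individual stores two associative strengths, `v_low` and `v_high`,
both initialized to the same very small value (`v_init = 0.01`, so initial
behavior is indifference, `p = 0.5`; any value $\le 0.1$ behaves
equivalently). Voting uses probability matching,
$p = v_{low} / (v_{low} + v_{high})$, with indifference returned when the
total strength falls below $10^{-12}$ (after long unrewarded stretches both
strengths can decay to zero and the ratio would be 0/0).

After each group decision, every cue whose signal pointed at the *chosen*
option is updated with the Rescorla–Wagner compound prediction error:

$$v \leftarrow v + \alpha\,\bigl(\lambda - (v_{low} + v_{high})\bigr),$$

clamped to `[0, 1]`, with learning rate $\alpha = 0.1$ and $\lambda \in
\{0, 1\}$ the shared outcome. Cues that pointed at the unchosen option are
untouched — an individual learns only about the option the group actually
experienced. When the two cues agreed and their option was chosen, both
update with the same error.

Measuring the error against the *total* prediction, rather than each
strength separately, is what makes the rule competitive, and the competition
is the scientific heart of the package. The strengths behave like shares of
a limited association: the cue whose agreement with the group's choices
predicts reward better takes over, and the other is driven toward zero
(where it sticks, because near-zero strength barely changes the total
prediction). The population therefore settles where

$$P(\lambda = 1 \mid \text{low cue agreed with the choice}) =
  P(\lambda = 1 \mid \text{high cue agreed with the choice}),$$

a melioration equilibrium in the sense of Herrnstein's matching literature.
Numerically this equilibrium tracks the optimal behavior $p^\*$ remarkably
closely for groups (e.g. 0.990 vs 0.991 at $n = 31$, $r_L = 0.7$,
$r_H = 0.75$) while producing graded probability matching in isolated
individuals — the full qualitative pattern the model is meant to exhibit. A
per-cue error $v \leftarrow v + \alpha(\lambda - v)$, by contrast, pins each
strength to a conditional reward rate in roughly $[0.7, 1]$, confining the
matched behavior to $p \in [0.41, 0.59]$ regardless of environment; it
cannot express exclusive cue use and we rejected it on those grounds. When
one cue's strength is zero the implemented update reduces exactly to the
textbook single-cue form.

Individual-level credit assignment is deliberately myopic: no individual
estimates group size, cue correlation, or reliability. The group-size and
correlation sensitivity of the learned behavior emerges from the gating
(only experienced options teach) and the shared outcome.

## Simulation protocols and their sizes

`run_training()` advances all replicate groups through the trial loop in one
vectorized stream: the default protocol is 500 replicates of 1000 trials,
with the mean behavior of the last 100 trials reported
(`summarize_learned()`, which also evaluates the exact accuracy of the
learned mean behavior — the deterministic quantity used for
fraction-of-maximum comparisons, so sampling noise cannot push a ratio above
one). The test suite and acceptance checks run 100 replicates instead of
500; at 100 replicates the Monte-Carlo error of a summary is already an
order of magnitude below the 5% tolerances used, and a full sweep finishes
in seconds.

`run_isolated_then_pooled()` trains agents at group size one, freezes their
learned behaviors, and evaluates the exact majority accuracy of pooled
groups via the Poisson-binomial kernel. Freezing isolates the comparison:
the question is what behavior learned *in isolation* is worth inside a
group, not how fast it would be relearned. Isolated learners never
experience group filtering, so they weight the low-correlation cue far less
than a group needs; pooling them yields accuracy near $r_H$ while
collectively trained groups approach the optimum, and the gap widens with
group size.

`run_transition()` changes the context after `change_trial` trials (500 in
the default protocol, 1000 trials total). A group-size increase pools agents
from `ceiling(n2/n1)` independently trained groups and keeps a uniform
subset of `n2`; a decrease keeps a uniform subset. A reliability transition
keeps the agents and switches `r_low` with `r_high` fixed. Learning
continues throughout; phase-2 success should be judged against the new
context's optimum, which the returned trajectory carries
(`optimal_accuracy_after`). Re-learning works because a strength parked at
zero re-enters competition as soon as the incumbent cue's reward rate drops
below the total prediction.

One RNG stream per run, seeded once: all randomness (superior options,
signals, mixed-strategy votes, tie breaks) is drawn from it, and identical
seeds reproduce trajectories bit for bit. Replicates are vectorized inside
the stream rather than given separate substreams; reproducibility is at the
run level, which is what the output manifests record.

## What the generator emulates — and what it does not

The trial generator *is* the model's informational environment: binary
options with a uniform prior, one perfectly shared signal, and
conditionally independent private signals at fixed reliabilities. Real
environments have graded correlation structure between these extremes,
unequal priors, more than two options and cues, reliabilities that drift
within a learning episode, and heterogeneous individuals. Passing tests
therefore demonstrate the internal consistency of this idealization — that
learning converges to the analytic optimum *of this environment* — not that
any particular animal system matches it quantitatively.

## The spatial validation

The consensus abstraction (majority with random tie-break) is validated by
a minimal zonal collective-motion model (`spatial_step()`, `run_bout()`):
individuals are repelled by neighbors inside 1 body length (repulsion
overrides everything, including preferences), attracted to and aligned with
neighbors within the outer zone, and blend that social vector with
`pref_weight = 0.5` times the unit vector toward their preferred target.
Headings turn at most `max_turn = 0.35` rad per step with Gaussian noise
(sd 0.05); speed is 1 body length per step. Two targets sit 50 body lengths
away, separated by 60°; a bout ends when everyone is within the capture
radius of a target or after 2000 steps, and arrived individuals freeze in
place (remaining visible as anchors for stragglers).

None of these magnitudes is prescribed by theory, so the defaults were
placed, once, in the cohesive schooling regime that the validation is
about: an outer zone of 10 body lengths and a capture radius of 8, a school
initialized polarized (headings toward the arena, dispersion 0.2 rad) and
equilibrated for 50 preference-free warm-up steps before the trial starts.
With a markedly weaker social field (outer zone ~7) or a cold random start,
the school frequently fissions before or during the approach — a real
regime of zonal models, but not the one whose consensus behavior is being
checked. Bout counts in the tests are 200 per preference fraction.
`summarize_bouts()` reports cohesion (the fraction of bouts with unanimous
arrival outcomes) and the majority-following curve over *decided* bouts;
bouts where nobody arrives, or arrivals tie, are excluded from the curve
and reported separately.

## Numerical choices, edge cases, limitations

* Degeneracy floor: conflict behavior is 0.5 when `v_low + v_high < 1e-12`.
* Even-`n` ties and threshold deadlocks always count $\tfrac12$.
* The optimizer is grid-plus-refinement; the stationarity condition and a
  $10^{-4}$ grid bound it in tests (`a_star` within $10^{-9}$ of any grid).
* Option labels are `"A"`/`"B"` at the interface, 0/1 internally; all
  decision probabilities are invariant to relabeling.
* Limitations: two options, two cues, equal per-individual reliabilities and
  learning rates, consensus enforced on every trial, equally shared reward.
  These are scope boundaries, not approximations — the analytics are exact
  within them.
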