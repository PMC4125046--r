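# collectivelearning

Tools for studying how associative learning interacts with consensus
decision-making in animal groups. Many social animals — fish schools, bird
flocks, primate troops — must repeatedly choose one option for the whole
group despite dissenting opinions. Consensus breaks the direct feedback
between an individual's preference and its experience: you learn about the
option the *group* chose, not the one you voted for. This package implements
a complete modelling framework for that situation, for behavioral ecologists
and collective-behavior modellers: exact voting-theory analytics, an
agent-based learning simulator, protocols for environment sweeps and
fission–fusion transitions, and a zonal collective-motion model that
validates the consensus abstraction.

## The model

A group of `n` individuals chooses between options A and B; one is superior
each trial (uniform prior). Two binary cues point at options:

* a **high-correlation cue** — one shared draw per trial, correct with
  probability `r_high`: when it errs, it errs for everyone;
* a **low-correlation cue** — independent per-individual draws, each correct
  with probability `r_low`.

Individuals vote for the option both cues indicate when they agree, and
under conflict follow the low-correlation cue with probability `p`. The
group takes the majority vote (ties random). Conditioning on the shared
signal makes voters conditionally independent with competence
`q1 = 1 − (1 − r_low)·p` or `q0 = r_low·p`, so the collective accuracy is
exact:

```
A(p) = r_high · M_n(q1) + (1 − r_high) · M_n(q0)
```

with `M_n` the Condorcet majority probability. `optimal_policy()` maximizes
`A(p)`; the optimum is exclusive low-cue use for most group environments, a
mixed strategy or exclusive high-cue use when the shared cue is reliable
enough. `global_optimal_accuracy()` benchmarks simple majority against the
globally optimal supermajority-threshold rule and the Nitzan–Paroush
full-information Bayes bound.

Learning is Rescorla–Wagner-style with a compound prediction error: each
individual keeps associative strengths `v_low`, `v_high`, votes by
probability matching `p = v_low/(v_low + v_high)`, and after every group
decision updates each cue that pointed at the chosen option by
`v ← v + α(λ − (v_low + v_high))`, where `λ` indicates whether the chosen
option was superior. The two strengths compete; the population settles where
the two cues' conditional reward rates equalize, which tracks the optimal
`p*` closely in groups while producing classic probability matching in
isolated individuals. See the methods vignette
(`vignettes/collective-learning.Rmd`) for the full account.

## Worked example

```r
library(collectivelearning)
env <- env_config(r_low = 0.7, r_high = 0.8)

optimal_policy(n = 25, env)
#> <policy_result> n = 25, r_low = 0.7, r_high = 0.8
#>   p* = 0.975629  accuracy = 0.983147  regime = mixed

traj <- run_training(env, n = 25, learning_config(n_reps = 100), seed = 1)
s <- summarize_learned(traj)
round(c(learned_p = s$learned_p, achieved = s$achieved_accuracy,
        optimal = optimal_policy(25, env)$a_star), 4)
#> learned_p  achieved   optimal
#>    0.9090    0.9779    0.9831

global_optimal_accuracy(n = 25, env)
#> <benchmark_result> n = 25, r_low = 0.7, r_high = 0.8
#>   simple majority + optimal p : 0.983147
#>   best (p, threshold m = 13)  : 0.983147
#>   full-information Bayes bound: 0.986356
```

Although the high-correlation cue is individually more reliable (0.8 vs
0.7), the best voting behavior for a group of 25 is to follow the
low-correlation cue almost always (`p* = 0.98`), because independent errors
can be outvoted. After 100 simulated training runs the learned behavior
(`p = 0.91`) achieves 97.8% accuracy against the 98.3% optimum — without any
individual knowing the group size or the cues' reliabilities. And
constraining the group to simple majority rule costs essentially nothing
relative to the globally optimal threshold rule (98.31% in both cases).

## Command line

A thin wrapper over the same functions lives at `inst/cli/collectivelearning`:

```sh
Rscript inst/cli/collectivelearning optimal --n 5 --r-low 0.7 --r-high 0.8
Rscript inst/cli/collectivelearning sweep --group-sizes 1,7,31 \
    --r-low-values 0.6,0.7,0.8,0.9 --r-high-values 0.6,0.7,0.8,0.9 \
    --n-reps 100 --seed 42 --output sweep.csv
```

Commands: `train`, `sweep`, `optimal`, `landscape`, `global-compare`,
`transition`, `isolated-pooled`, `spatial-validate`. Configuration can come
from a YAML/JSON file (`--config`), with flags taking precedence; outputs are
CSV with a sibling JSON manifest recording config, seed and package version,
so every run is reproducible from its outputs. Output columns are snake_case
(`n`, `r_low`, `r_high`, `learned_p`, `achieved_accuracy`, `optimal_p`,
`optimal_accuracy`, `fraction_of_max`, ...).

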