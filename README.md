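# paradigmflow

Agent-based simulation of paradigm shifts in a community of knowledge.

A homogeneous community of `n` researchers explores a fixed one-dimensional
"physical-technological" landscape `V(x)`: each position `x` is a theory or
technology, and `V(x)` its performance or predictive power. The landscape is
an inverted double-well quartic

```
V(x) = a (−x (x+b) (x−c) (x−d) + e)
```

with a local optimum `x_old` (the current paradigm), a valley bottom
`x_barrier` (the cost of transition) and a higher global optimum `x_new`
(the new paradigm). Its gradient factors as
`V'(x) = −γ (x−x_new)(x−x_barrier)(x−x_old)` with `γ = 4a`; the defaults
(`a = 10⁻²`, `b = 2`, `c = 1`, `d = 6`, `e = 2·10²`) give `γ = 0.04` and
critical points near −1.27, 0.5 and 4.5.

Each agent `i` follows the Langevin-type evolution equation

```
dx_i/dt = (1 − α) V'(x_i)  +  α ω g(x_i, x_j)  +  ε ξ(t)
```

combining **individual search** (gradient ascent on `V`), **social
influence** `g(x_i) = (1/m) Σ_j [V(x_j) − V(x_i)] (x_j − x_i)` over `m`
peers sampled each step (attraction toward better-performing peers,
repulsion from worse), and **experimentation** (Gaussian white noise of
strength `ε`). The weight `α ∈ [0, 1]` interpolates from purely individual
(`α = 0`) to purely social (`α = 1`) learning; `ω` scales the relative
strength of the social term.

The headline output is the community shift time `t_s`: the first time at
which *every* agent has migrated from `x_old` to the neighbourhood of
`x_new`. Its mean over replicates, as a function of `α` and `n`, exhibits
three regimes — a steep drop at small `α`, a conservative rise at
intermediate `α` (peaking near `α ≈ 0.7`), and a return toward the baseline
as the community starts migrating collectively — with an optimum at a small
but positive social-influence weight. Simulation is synchronous
Euler–Maruyama (default `dt = 0.01`) with a compiled core; agents that have
arrived at the new paradigm can never migrate back (reflection at the
valley bottom).

## Worked example

```r
library(paradigmflow)

ls <- quartic_landscape()
critical_points(ls)
#> x_old = -1.268381, x_barrier = 0.526562, x_new = 4.491819
#> gamma = 0.04, barrier_from_old = 0.187474, gain = 1.382657
```

The community starts at the old optimum; `barrier_from_old ≈ 0.19` is the
performance dip an agent must cross, and `gain ≈ 1.38` the reward at the
new paradigm. One realization at a small social-influence weight:

```r
p <- dynamics_params(alpha = 0.15)
rec <- simulate_trajectory(ls, p, n = 12, seed = 1, record_every = 100)
community_shift_time(rec)
#> $t_s
#> [1] 108
#> $censored
#> [1] FALSE
```

All 12 agents reach the new paradigm by `t ≈ 108` — pioneers cross the
valley first, then pull the rest across (the follow-the-leader effect;
`plot_trajectories(rec)` shows it). Sweeping `α` reveals the three regimes:

```r
sw <- alpha_sweep(ls, dynamics_params(), alphas = seq(0, 1, 0.1),
                  ns = 12, reps = 20, master_seed = 7)
regime_summary(sw)
#>    n three_regimes alpha_min alpha_max                       note
#> 1 12          TRUE       0.2       0.7 decrease-increase-decrease
```

Mean shift time drops from `α = 0`, is minimized at small `α`, peaks near
`α = 0.7` (the most conservative community), and falls again toward
`α = 1`; `plot_sweep(sw)` draws the curve with standard-error bars. At
`α = 0` shifts are independent single-agent escapes
(`single_agent_oracle()` gives the baseline distribution); finer grids and
more replicates (`reps = 200` per cell is the default experiment
configuration) localize the optimal weight.

A thin command-line interface over the same functions lives at
`inst/cli/paradigmflow` (subcommands `describe-landscape`, `simulate`,
`sweep`, `regimes`, `oracle`, `plot`, each taking `--config`, `--seed`,
`--out`); configuration files are JSON with sections `landscape`,
`dynamics`, `experiment`, `output`.

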