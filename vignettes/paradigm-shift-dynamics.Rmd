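---
title: "Collective search and paradigm shifts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective search and paradigm shifts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paradigmflow)
```

## The model

A community of `n` identical agents searches a fixed, one-dimensional
"physical-technological" landscape. A position `x` stands for a theory or
technology; its height `V(x)` for predictive power or performance. The
landscape is the inverted double-well quartic

$$V(x) = a\left(-x\,(x+b)(x-c)(x-d) + e\right),$$

whose gradient is a cubic with three real roots,
$V'(x) = -\gamma\,(x - x_{new})(x - x_{barrier})(x - x_{old})$ with
$\gamma = 4a$ exactly. The left hill ($x_{old}$) is the current paradigm, a
local optimum; the right hill ($x_{new}$) the new, superior paradigm; the
valley between them is the transition cost. With the default coefficients
($a = 10^{-2}$, $b = 2$, $c = 1$, $d = 6$, $e = 2\times 10^2$):

```{r landscape}
cp <- critical_points(quartic_landscape())
cp
```

Each agent evolves by

$$\frac{dx_i}{dt} = (1-\alpha)\,V'(x_i) \;+\; \alpha\,\omega\,
g(x_i, x_j) \;+\; \varepsilon\,\xi(t),$$

with $g(x_i) = \tfrac1m \sum_j [V(x_j) - V(x_i)](x_j - x_i)$ over $m$ peers
sampled uniformly without replacement each step, and $\xi(t)$ zero-mean
Gaussian white noise. The three forces are individual hill climbing
(agents only sense the local slope), social influence (attraction toward
better-performing peers, repulsion from worse ones, stronger for more
distant peers), and random experimentation, which alone enables barrier
crossing. The community shift time $t_s$ is the first time every agent has
reached the neighbourhood of $x_{new}$; its mean over replicates, as a
function of $\alpha$ and $n$, is the model's headline output.

## Parameters

| parameter | default | meaning |
|---|---|---|
| $\alpha$ | — | weight on social influence, in $[0,1]$ |
| $\omega$ | 3.14 | strength of social relative to individual information |
| $\varepsilon$ | 0.37 | experimentation (noise) strength |
| `dt` | 0.01 | Euler–Maruyama step, model-time units |
| `m` | $n-1$ | peers sampled per agent per step |
| `t_max` | $10^5$ | censoring horizon |
| `arrival_delta` | 0.5 | arrival band: $x \ge x_{new} - \delta$ counts as arrived |
| `jitter_sd` | 0 | spread of the initial condition around $x_{old}$ |

The defaults for $\omega$ and $\varepsilon$ are the model's standard
operating point; they
balance the model so that purely individual ($\alpha=0$) and purely social
($\alpha=1$) search take similar mean shift times, which the acceptance
suite verifies. All quantities are dimensionless; time is in units of the
continuous equation, so only relative and shape comparisons across
$\alpha$ and $n$ are meaningful. The experiment defaults ($n \in \{12, 24,
36\}$ with $m = n-1$, 200 replicates per parameter combination, $\alpha$
from 0 to 1) are the conditions under which the three-regime curve is
established.

## Numerical choices

**Integration.** The continuous equation is discretized by synchronous
Euler–Maruyama: all drifts are evaluated at the pre-step positions, then
$x_i \leftarrow x_i + \text{drift}\cdot dt + \varepsilon\sqrt{dt}\,z_i$
with independent standard-normal $z_i$. This is the minimal-bias
discretization of a Langevin equation; a convergence test checks that the
mean single-agent first-passage time moves by less than 5% when `dt` is
halved to 0.005. A stability guard rejects any run whose initial
$|\text{drift}|\cdot dt \ge 0.5$, and the integrator aborts on non-finite
positions rather than continuing silently.

**Root finding.** Critical points are the eigenvalues of the companion
matrix of $V'/(-4a)$, polished by Newton iterations to $10^{-10}$ and
cross-checked in the tests against `polyroot`. The printed one- and
two-decimal values (−1.27, 0.5, 4.5) are roundings of the full-precision
roots (−1.268381, 0.526562, 4.491819), which the package reports and uses
everywhere; rounding happens only for display. The middle root is 0.527 to
three decimals, i.e. 0.5 at one decimal.

**Initial condition.** "The community starts at the current paradigm" is
resolved as all agents exactly at $x_{old}$; a configurable Gaussian
jitter (default sd 0) is available for robustness checks. Exact placement
maximizes reproducibility and makes the noise-free case an exact fixed
point.

**The no-return rule.** Back-migration from the new paradigm is excluded
by construction: an agent that has *arrived* (reached
$x_{new} - \delta$) and whose proposed position falls below the valley
bottom is reflected there ($x \leftarrow 2x_{barrier} - x$). The latch is
deliberately placed at arrival rather than at the first crossing of the
valley bottom. With a crossing latch, every grazing contact with
$x_{barrier}$ is irreversible; at high $\alpha$ the socially-bound
community's stationary spread touches the barrier often enough that the
community escapes at single-agent speed, which erases two signature
behaviours: the third (decreasing) regime beyond $\alpha \approx 0.7$ and
the similarity of mean shift times at $\alpha = 0$ and $\alpha = 1$. With
the arrival latch a would-be pioneer that has merely crossed the valley
can still be pulled back by the conservative social force of the
old-paradigm majority — exactly the tension the model is about — and both
signatures appear (extreme-$\alpha$ ratio ≈ 1, conservative peak near
$\alpha = 0.7$). Alternatives (absorption at $x_{new}$, rejection
sampling) would behave nearly identically since arrived agents sit in a
strong basin far from the barrier.

**Peer sampling.** Peers are redrawn for every agent at every step. At the
default $m = n-1$ the sample is the whole rest of the community and the
social term is computed by an exact $O(n)$ telescoped sum in the compiled
core; for $m < n-1$ a partial Fisher–Yates draw is used. The pure-R
reference stepper (`em_step`) and the compiled core consume R's RNG stream
in the same order, so trajectories agree to floating-point rounding and
repeated runs with one engine are bit-identical.

**Censoring.** Replicates in which some agent never arrives by `t_max`
report `t_max` as a lower bound and are excluded from cell means, with the
censored count published alongside; a Kaplan–Meier restricted mean
(`km_mean_shift_time`) is available for heavily censored cells. Under the
default conditions censoring is absent for all $\alpha$ at $n \le 36$.

**Seeds.** A master seed deterministically spawns one seed per sweep cell
and per replicate, so results are independent of execution order and each
output manifest can regenerate its table exactly.

**Regime detection and the optimal weight.** Mean-shift-time curves are
first smoothed with a centered 3-point moving average (shrinking at the
edges) so that Monte-Carlo jitter is not classified as structure. The
three-regime summary finds the first interior local minimum and the
subsequent local maximum, and requires the curve to descend after the
maximum; anything else is flagged (`no three-regime structure`,
`inconclusive`) rather than forced. The optimal social-influence weight is
the grid argmin of the smoothed curve. On the fine grid ($\Delta\alpha =
0.025$, $n = 12$, 50–200 replicates) the smoothed argmin lands at
$\alpha = 0.075$ reproducibly across master seeds, with the curve flat to
within one standard error over $\alpha \in [0.05, 0.125]$ — so the
well-supported statement is that the optimum is a small positive weight in
the 5–13% band, its exact grid location being resolution- and
noise-limited.

## What the simulations do and do not show

The generator *is* the model: there is no external data, and every
empirical claim in this package is a property of the stochastic process
above at the stated parameters. Passing tests therefore demonstrate
internal consistency (discretization accuracy, independence at $\alpha =
0$, comparative statics of the barrier, the three-regime shape), not that
real scientific communities behave this way. Features of real communities
deliberately outside the model: agents have no memory, the community is
homogeneous and fully mixed (no network structure), the landscape is
fixed, one-dimensional and commensurable across paradigms, and noise is
stationary Gaussian.

## Problem sizes

The shipped tests run the full-width sweep at 50 replicates per point and
the extreme-$\alpha$ and independence checks at 100–200 replicates —
enough that every qualitative assertion is stable across seeds while the
whole suite completes in minutes; the acceptance script uses the full 200
replicates per grid point. Larger batches only narrow standard errors
(they scale as $1/\sqrt{reps}$) and can be requested through the `reps`
arguments throughout.

## Known limitations

* Absolute times depend on the discretization and are reported in model
  units; only shapes, orderings and argmin locations are comparable across
  implementations.
* At $m < n - 1$ the compiled and reference engines use different
  sampling-stream layouts and agree only in distribution.
* The landscape must be a genuine double hill; degenerate coefficient
  choices (coincident roots) are rejected rather than repaired.
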