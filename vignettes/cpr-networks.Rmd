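---
title: "Common-pool resource games on information networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common-pool resource games on information networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprnet)
```

## The model

`cprnet` simulates a population of `P` users of a common-pool resource
(a fishery, a forest, an aquifer) who repeatedly choose between **low-effort**
and **high-effort** extraction. Three coupled layers drive the dynamics.

**The game.** Payoffs interpolate linearly between a degraded environment
(`n = 0`) and a prosperous one (`n = 1`) and depend on the fraction `z` of
others expected to extract with low effort:

$$\pi_L - \pi_H \;=\; (1-n)\,\big(\delta_{L0}\,z + \delta_{H0}(1-z)\big)
  \;-\; n\,\big(\Delta_{L1}\,z + \Delta_{H1}(1-z)\big).$$

The four corner incentives are the game's sufficient statistics; absolute
payoff levels are gauge freedom. The defaults
(`deltaH0 = 0.3, deltaL0 = 0.05, DeltaL1 = 0.7, DeltaH1 = 0.45`) create
*anti-coordination* incentives: high effort pays more the more others are
expected to extract gently and the richer the resource. Along the diagonal
`z = n` the advantage reduces to `0.3 - n`, so the **full-information
equilibrium** (FIE) — the state a perfectly informed, well-mixed population
would reach — sits at `n* = z* = 0.3`, with 70% of users on high effort.

A note on the sign of `deltaH0`. The anti-coordination setting requires the
early-adopter advantage of low effort in a depleted environment to be
positive, and only `+0.3` makes all four tabulated incentives consistent
with an interior equilibrium at `n* = 0.3`. The package therefore uses
`+0.3` as its default; `default_payoffs(as_printed = TRUE)` exposes the
alternative `-0.3`, under which `solve_fie()` correctly reports that no
interior equilibrium exists. Three equivalent parameterizations (corner
payoffs, incentive differences, affine coefficients) are interconvertible
through exact mapping functions and agree to machine precision.

**The information network.** Agents observe only their network neighbours.
`generate_ba(P, lam)` builds the preferential-attachment graph: `lam`
initially isolated seed nodes, then `P - lam` nodes added one at a time,
each linking to `lam` distinct existing nodes with probability proportional
to current degree (the first added node's attachment is forced, since all
candidates start with degree zero). Large `lam` produces extreme skew — at
`P = 1000, lam = 950` the 50 added nodes become hubs of degree ≥ 950 while
the 950 seed nodes end with about 48–50 links. Successive
degree-proportional draws without replacement are realized with
exponential-key weighted sampling, which is distributionally identical to
the textbook urn-with-rejection scheme but does not degenerate when `lam`
approaches the number of candidates. Skewness is summarized by the
Fisher–Pearson statistic `m3 / m2^{3/2}` of the degree sequence (the
statistic is a package choice; sweep outputs also record `lam` so results
can be re-keyed).

**Expectations.** Agents are boundedly rational forecasters. Whenever an
agent acts it snapshots its ledger — the impact-weighted fraction of its
neighbours currently on low effort — and feeds its snapshot history to four
forecasting rules: adaptive, trend-chasing, contrarian
(`beta3 < 0`), and anchoring-and-adjustment. Every rule's fitness is a
geometrically discounted sum of negated squared forecast errors, updated
for all four rules at every action event; the rule in use is retained with
inertia `rho` and otherwise re-drawn from a softmax over fitnesses with
intensity `phi` (computed max-shifted: at `phi = 100` raw exponentials
overflow). Time subscripts in the rules are **event time** — an agent's own
successive actions, on average one per `P` scheduler steps — because
snapshots exist only at action events. The adaptive rule blends the newest
snapshot with that rule's own previous forecast (the standard adaptive-
expectations reading). Forecasts are population fractions and are clipped
to `[0, 1]`; the trend, contrarian and anchoring rules can otherwise exit
the unit interval.

**Decisions and the resource.** The scheduler draws one agent per step.
The agent evaluates the advantage of high effort `A_H = \pi_H - \pi_L` at
its forecast `z^e` and its private perceived resource state, then chooses
high effort with probability `1 / (1 + exp(-d \sigma A_H))`: degree `d`
sharpens the response, so hubs act near-deterministically on small
advantages while leaves stay noisy. (The exponent is oriented so that a
higher perceived advantage of high effort makes high effort more likely,
and is clipped at ±500.) The effective extraction level is the
impact-weighted low-effort share `z = Σ S_i W_i` with
`W_i ∝ d_i^ν`; the resource closes a share `ε/P` of its gap to `z` each
step; and every agent's perceived resource state crawls toward its local
observation at the same `ε/P` rate. All state variables are convex
combinations of quantities in `[0, 1]` and provably stay there.

**Impact-weighted observation.** An agent's ledger snapshot weights each
neighbour by `d^ν`, the same exponent that sets environmental impact. This
is the natural estimator — the quantity agents forecast is the *effective*
extraction level, which is itself `d^ν`-weighted — and it is what makes the
impact-inequality mechanism work: at `ν = 0` the snapshot is the plain
neighbourhood mean and hub visibility biases everyone's perception (the
majority illusion); as `ν` grows the truth itself becomes hub-weighted, so
the hub-biased local view becomes *accurate* and outcomes contract toward
the full-information equilibrium. We verified that leaving snapshots
unweighted breaks this contraction: `ν` then never enters any agent's
information set, the sorted state persists unchanged, and the weighted
resource is simply dragged away from the equilibrium.

## Default configuration

| parameter | default | meaning |
|---|---|---|
| `P` | 1000 | population size |
| `T` | 40000 | scheduler steps (40 generations) |
| `lam` | 250 | attachment count of the network generator |
| `nu` | 0 | inequality of environmental impact |
| `epsilon` | 0.25 | relative speed of environmental vs strategic dynamics |
| `sigma` | 0.1 | slope of the logistic choice rule |
| `beta1, beta2, beta3` | 0.63, 0.44, −0.44 | forecasting-rule coefficients |
| `rho` | 0.9 | heuristic inertia |
| `eta` | 0.7 | fitness memory |
| `phi` | 100 | choice intensity of the heuristic softmax |
| `n0, p_low0` | 0.5, 0.5 | symmetric initial conditions |

One *generation* is `P` steps (one expected action per agent). The
environment's relaxation timescale is `P/ε = 4000` steps, i.e. four
generations. Initial conditions are symmetric so that the starting point
does not bias the long-run branch; we verified that starting at the
equilibrium or from a depleted state leaves the long-run outcome unchanged.

## Initialization and random numbers

A run is fully determined by `(config, seed)`. The seed drives, in fixed
order: network generation, iid Bernoulli(`p_low0`) initial strategies,
uniform initial heuristics; the simulation loop then consumes exactly three
uniforms per step (agent selection, heuristic selection, action). Agents
cold-start with their history and all four forecasts set to their initial
local observation and zero fitnesses — an unbiased start. Ensembles use
seeds `base, base + 1, …`, so each run has its own network *and* its own
decision noise.

The production engine is compiled; a pure-R reference engine composes the
exported module functions in the same draw order and is tested to replay
the compiled engine exactly (integer outputs identical, floating outputs to
rounding). Graphs with isolated nodes are rejected at setup: an agent with
no neighbours has no information set.

## Analytics

`classify_outcome()` labels a run *scarce* when its mean resource state
over the final 100 un-strided steps lies strictly below `n*` (ties count as
abundant). `sweep_skewness()` re-runs ensembles over a `lam` grid (default
`{50, 150, …, 950}`) and `sweep_impact()` over `ν ∈ {0, 0.25, …, 3}`;
both key outputs by `(sweep value, seed)`. `effort_degree_correlation()`
(Pearson correlation of the high-effort indicator with degree; 0 by
convention for constant strategies) tracks the emergent sorting of
strategies by connectivity, and `majority_illusion_index()` counts agents
whose neighbourhood majority contradicts the population majority
(neighbourhood ties resolve toward the population majority; a population
tie counts low effort as majority).

The analytical companion is the replicator flow with environmental
feedback, `dz/dt = z(1-z)(\pi_L - \pi_H)`, `dn/dt = ε α (z - n)`,
integrated with a fixed-step RK4 scheme (`deSolve`); `α = 1/P` matches the
per-step gap closure of the discrete law of motion. Its interior fixed
point `(0.3, 0.3)` is locally stable (numerically verified eigenvalues),
and the well-mixed full-information control of the agent-based model — a
complete graph — settles within a few hundredths of it.

## What the simulations do and do not reproduce

The simulator reproduces, and the test suite checks:

* the full-information equilibrium at `n* = 0.3` (70% high effort), in
  closed form and by bisection;
* the construction facts of the extreme-skew network (50 hubs of degree
  ≥ 950, 47500 edges, leaf degrees 48–50) and growth of degree skewness
  with `lam`;
* emergent sorting of effort by degree whose sign persists within a run,
  hub-biased perception (majority illusion), and near-deterministic hub
  decisions;
* **alternative stable states**: seeding the mirror configuration
  (top-degree nodes on low effort, depleted resource) yields a persistent
  scarce state, and the gap between the two branches widens with degree
  skewness and shrinks toward the equilibrium as impact inequality `ν`
  rises;
* convergence of the complete-graph control to the equilibrium with no
  bimodality, and agreement of the near-equilibrium behaviour with the
  replicator flow.

One empirical signature is *not* reproduced: with the symmetric defaults,
independent runs essentially always settle on the abundant branch
(≈ 0.40) rather than splitting roughly one-third scarce / two-thirds
abundant. The package's own diagnosis, which the instrumentation in
`run_sim(..., diagnostics = TRUE)` makes repeatable: under the logistic
choice rule, the stochastic steady state balances `z = 1 - E[P_H]`, and at
the zero-advantage point that expectation is one half — more low effort
than the 30% the equilibrium requires. The population therefore hovers
slightly **above** the zero-advantage line (measured mean advantage of high
effort ≈ +0.02 against a cross-agent dispersion of ≈ 0.015 at the critical
phase), and the sharp-responding hubs lock onto high effort in essentially
every realization. Because both branches are demonstrably stable once
entered, the split frequency is a property of the *symmetry-breaking
transient*, and is highly sensitive to unprinted implementation details of
expectation cold-starts and decision timing. We report the honest computed
rate rather than tuning toward a target.

## Problem sizes used by the tests

Unit tests run the reference-vs-compiled replay and schedule checks at
`P = 30, T = 600`. The acceptance checks use the full default problem size
for single runs and sweeps (`P = 1000, T = 40000`; 10 runs per `ν` level on
the grid `{0, 1, 2, 3}`), a 50-seed default ensemble for the branch split,
a 500-node complete graph over 30000 steps for the full-information
control, and 10 network seeds for the construction facts. The acceptance
script reruns the 100-seed default ensemble from scratch.

## Known limitations

* The network is fixed: no rewiring, clustering or community structure,
  and visibility is symmetric and unweighted by tie strength.
* The resource law of motion is linear relaxation; no regrowth
  nonlinearity, collapse threshold or spatial structure.
* The heuristic menu is the four standard rules with homogeneous
  coefficients and no switching costs.
* The spontaneous branch-split frequency at the symmetric defaults is not
  reproduced (see above); bistability itself, and every comparative static
  around it, is.
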