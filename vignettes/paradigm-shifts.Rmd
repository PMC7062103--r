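---
title: "Modelling cultural paradigm shifts on epistatic fitness landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cultural paradigm shifts on epistatic fitness landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturedyn)
```

## The model

`culturedyn` studies how the culture of a large, well-mixed population
responds to slow environmental change. An individual's culture is a vector of
`n` binary traits, so the population lives on the `2^n` vertices of a
hypercube; `x(s, t)` is the fraction of the population holding trait
combination `s`. Each combination has a *fitness* `F(s)` in `[0, 1]`,
understood as internal consistency: how free of cognitive dissonance an
individual in state `s` is, and hence how reluctant to change.

Three ingredients drive the dynamics:

* **Fitness-biased adoption.** When an individual in state `s'` considers
  switching one trait to reach `s`, they do so with probability
  `G(F(s)/F(s')) = r^beta / (1 + r^beta)`. The sharpness `beta > 0` measures
  intolerance of dissonance: `beta` large means fitness-increasing changes
  are adopted almost surely and fitness-decreasing ones almost never;
  `beta` small means tolerant, exploratory individuals. `G(1) = 1/2`,
  `G(0) = 0`.

* **Horizontal contagion with optional homophily** (rate weight `lambda`).
  Individuals meet pairwise and put one random trait at stake. The influence
  of a peer at Hamming distance `d` is
  `W(d) = (d/n) (1 - d/n)^alpha (1+alpha)^(1+alpha) / alpha^alpha`,
  normalized so its maximum over real `d` is 1, attained at
  `d = n/(1+alpha)`. With `alpha = 0` (the default) `W = d/n` is just the
  probability that the discussed trait differs; larger `alpha` concentrates
  influence on culturally closer peers.

* **Guided variation** (rate weight `mu`): spontaneous single-trait changes,
  biased by the same sigmoid. Defaults `lambda = 0.999`, `mu = 0.001` make
  99.9% of changes transmission-driven; the `mu` term mainly prevents states
  from dying out irreversibly.

Only one trait can change per event, so probability flows along hypercube
edges. The balance of inflow and outflow gives a coupled ODE system over the
viable states.

### Landscapes, epistasis and incompatibility

Fitness comes from Kauffman's NK construction: `F(s)` is the mean of `n`
component tables, each reading a cyclic window of `k + 1` traits, with all
table entries drawn uniformly on `[0, 1)` from a seed. `k = 0` gives an
additive, single-peaked landscape; `k >= 1` introduces epistasis (the worth
of one trait depends on others), producing rugged, multi-peaked landscapes;
`k = n` is a fully random landscape. A second, qualitatively different form
of epistasis is *trait incompatibility*: thresholding at `f_th` sets
`F_th(s) = F(s) - f_th` when `F(s) > f_th` and 0 otherwise, and zero-fitness
states carry no population at all. `threshold_for_count()` picks the
threshold producing a prescribed number of incompatible states (the standard
configuration uses 24 of 64).

Slow environmental change is a convex combination
`F_tau = tau F1 + (1 - tau) F0` of two independently seeded landscapes with
the same parameters. As `tau` moves from 0 to 1 in steps of `eps = 0.01`,
consecutive landscapes are almost indistinguishable — every sweep records the
step-to-step landscape similarity, which stays above 0.999 — yet the
population can respond discontinuously. Trait incompatibilities are treated
as environment-independent: the incompatible set is frozen across all `tau`.
Which endpoint defines that set is genuinely underdetermined; we default to
deriving it from `F0`, with `F1`, union and intersection variants available
through `incompatible_from`. An explicit `f_th` is applied identically to
both endpoints. When the threshold is specified as a *count* of incompatible
states, each endpoint is thresholded at its own `m`-th smallest fitness
value: a single threshold derived from `F0`'s quantile occasionally exceeds
every fitness in `F1` (the two landscapes are independent draws), which
would collapse the `tau = 1` endpoint to identically zero fitness;
per-endpoint quantiles give both endpoints exactly `m` zero-fitness states
for every seed.

### Measuring cultural change

Populations are compared with a Hamming-kernel inner product,
`<x, y> = sum_{s,s'} x(s) [n - d_H(s, s')] y(s')`, and the similarity
`sim(x, y) = <x, y> / sqrt(<x,x> <y,y>)`. We read the denominator as the
geometric mean of the self-products — the only reading for which
`sim(x, x) = 1` and the worked two-trait examples (`1/2` for adjacent
indicator populations, `0` for antipodal ones) hold. Unlike a plain dot
product, this similarity credits populations whose mass sits on *nearby*
states, so a drop in `sim(x_tau, x_{tau - eps})` signals a genuine
relocation of the population across the hypercube.

## Numerical procedure

The equations are integrated in log densities `y(s) = log x(s)` — which keeps
every viable fraction positive no matter how small — with a fixed-step
fourth-order Runge–Kutta scheme at `dt = 0.1`. Equilibrium is declared when
the population changes by less than `1e-4` in max norm over a window of 100
time units, checked every window. A sweep equilibrates at each `tau`,
warm-starting from the previous equilibrium; the first grid point starts
from the uniform distribution on viable states.

Numerical choices worth knowing about:

* The homophily-weighted peer sums are XOR-convolutions on the hypercube and
  are evaluated with Walsh–Hadamard transforms (`O(n 2^n)` per derivative),
  with a dense-kernel R implementation kept alongside as a cross-check; the
  two give identical results to machine precision, and the compiled
  trajectory is additionally tested against an independent direct-in-x RK4
  oracle at a tenth of the step (agreement better than `1e-6` over 100 time
  units).
* Mass is conserved only approximately by the log-space step (drift below
  `1e-6` per 10^4 time units); the equilibrium vector is renormalized to unit
  sum once at the end of each equilibration, not during integration.
* The stopping rule has no intrinsic time bound; a configurable safety cap
  (`max_time`, default `1e5`) turns a stalled run into an error carrying the
  last state and residual. Near tipping points the population can take a few
  times `1e4` time units to cross between basins, which the default
  accommodates.
* Initial conditions concentrated on a few states have enormous log-space
  derivatives at the nominal step. The integrator detects this and briefly
  substeps (halving `dt` until a single update moves no log density by more
  than 2, then doubling back), which affects nothing but the first fraction
  of a time unit of such runs; uniform and warm starts are untouched.
  Initial conditions with exact zeros on viable states are floored at
  `1e-12` by `run_initial_conditions()` (log variables cannot represent 0).
* With `lambda = 0` the model satisfies detailed balance and the equilibrium
  is exactly proportional to `F^beta`; the suite verifies the integrator
  against this closed form. Those runs use `mu = 1`: with transmission off,
  `mu` only rescales time, and leaving it at `0.001` would make relaxation so
  slow that the 100-time-unit stopping window could trigger before
  equilibrium.
* Exact fitness ties (probability zero under the NK construction) are
  handled strictly: the local-maximum census requires strict superiority and
  warns when ties occur, so a constant landscape has no peaks and the flat
  floor of the two-peak fixture triggers a documented warning.

## The quasi-static experiments

`run_sweep()` drives `tau` forward (or backward) across `[0, 1]`,
`run_hysteresis()` chains a forward sweep and a warm-started backward sweep,
`run_initial_conditions()` relaxes several initial populations on one fixed
landscape, and `run_ensemble()` repeats sweeps over seeded landscape pairs
(seeds `seed, seed + 1, ...`).

Jumps are detected where the step similarity `sim(x_tau, x_{tau-eps})` falls
below a threshold (default 0.9), and a loop is called hysteretic when the
forward and backward similarity curves differ pointwise by more than 0.05
somewhere. The source material reports jumps and hysteresis visually, so
both cutoffs are this package's own operational definitions; they are
configuration-exposed and reported with every result. As a
threshold-independent size measure, ensembles also record the largest
single-step drop of `sim(x_0, x_tau)` and its location.

```{r sweep-example, eval = FALSE}
pair <- landscape_pair(6, k = 1, seed = 101)
sw <- run_sweep(pair)
glance(sw)
autoplot(sw)
hy <- run_hysteresis(pair)
glance(hy)
```

## What the generator emulates — and what it does not

Seeded NK landscape pairs *are* the study conditions: six binary traits,
epistasis `k`, optionally 24 incompatible states, `beta = 1`, `alpha = 0`,
`lambda = 0.999`, `mu = 0.001`, `eps = 0.01`. Within them the package
reproduces the model's characteristic phenomenology: smooth cultural change
without epistasis; abrupt, hysteretic paradigm shifts with even weak
epistasis or with incompatibilities; smaller and earlier jumps at low
`beta`; jumps that survive homophily. The *locations* of individual tipping
points are properties of particular random landscape realizations and are
not reproducible quantities — only the statistics over seeds are.

No claim extends beyond the model: real cultural data involve finite
populations (demographic noise), spatial and network structure,
time-varying and heterogeneous learning rates, innovation that enlarges the
trait repertoire, and non-binary traits — all outside this package's scope,
as they are outside the model's.

## Problem sizes used by the test suite

Analytic anchors (similarity worked examples, sigmoid and homophily
normalizations, state numbering) are exact and instantaneous. The
detailed-balance check runs 20 three-trait landscapes at three values of
`beta`; the integrator cross-check runs the fixed two- and three-trait
oracle systems. The phenomenology suite uses ensembles of 10 seeded pairs at
`k = 0` (with full forward/backward loops), 12 at `k = 1`, and 30 at `k = 0`
with 24 incompatible states, plus `beta = 0.1` re-sweeps of every jumping
`k = 1` seed and `alpha` ∈ {1, 5} re-sweeps of one. These sizes are the
package's standard verification settings, chosen to exercise every claim
with clear statistical margins while keeping a full run of the suite in the
tens of minutes on one core; `run_ensemble()` scales to larger ensembles
unchanged.

## Known limitations

* The quasi-static grid scan locates transitions only to within `eps`; no
  continuation or bifurcation-tracking is attempted (deliberately, as the
  scan *is* the protocol).
* The fixed-step explicit scheme is not suitable for stiff extremes such as
  `mu >> 1` with `dt = 0.1`; rate weights should be kept of order one
  (e.g. normalize `lambda + mu = 1` when exploring the `mu/lambda` ratio).
* State-space size grows as `2^n`; a guard rails `n` at 16 by default.
  Everything is exact in the number of states — there is no sampling error,
  only integration error.
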