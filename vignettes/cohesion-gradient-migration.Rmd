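---
title: "Cohesion-gradient-driven cluster migration: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohesion-gradient-driven cluster migration: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cohesim)
```

## The question the model addresses

Clusters of neural progenitor cells migrate persistently up a growth-factor
gradient while the same cells, alone, wander without direction. The growth
factor is known to upregulate cadherin expression, i.e. cell–cell cohesion,
so a cluster sitting in a linear gradient carries a *linear internal
cohesion gradient* from its trailing to its leading edge. `cohesim` asks
the minimal mechanical question: can that internal asymmetry alone, with no
external force gradient and no polarised protrusions, move the cluster?

The model's answer, which the test suite and acceptance script reproduce
quantitatively, is yes — but only when protrusions are stochastic, only
when the leading cells are more closely packed than the protrusion length,
and only when interior cells protrude much less than the outermost ones.

## Model

### Agents and bonds

`N` cells are unit-mass, unit-radius spheres on the gradient axis
(`r = m = dt = 1`; all quantities are in these computational units, and
speeds are reported in mr/τ = 10⁻³ radii per timestep). Neighbouring cells
are joined by viscoelastic bonds formulated in *gap coordinates*
`g = x[i+1] − x[i] − 2r`, so that the just-touching configuration `g = 0`
is the zero-stress rest state. The published per-agent force equations are
linear in absolute positions, which has no rest length and would collapse
the chain; re-expressing them in the gap restores the intended "relax back
to just touching" behaviour. For the same reason we use the dissipative
sign for the bond-viscosity term in both rheologies.

Tension and compression use different moduli: the tensile stiffness `Ka`
(the cadherin-mediated cohesion, position-dependent) acts when `g > 0`, the
repulsive stiffness `Kr` (hydrostatic/cytoskeletal) when `g < 0`; exactly
one is active at any instant. A bond whose gap exceeds `zone_max` is
detached and exerts no force — this is what lets the weakly tethered
trailing cell wander almost independently.

* **Kelvin–Voigt (KV)**: `σ = K1·g + η_i·ġ`, applied `+σ` to the trailing
  and `−σ` to the leading member.
* **Standard Linear Solid (SLS)**: a series spring `K2` adds creep with
  time constant `τ = η/K2`. Each bond integrates
  `g⃛ = −(K1/τ)·g − (K1+K2)·ġ − g̈/τ` as its own dynamic state (the
  third-order memory lives on bonds, not agents, following the pairwise
  constitutive law), and applies `∓g̈/2` to its two members, so paired
  contributions cancel exactly and internal forces can never move the
  centre of mass. A detached SLS bond relaxes its stress memory as
  `dg̈/dt = −g̈/τ`. Note the bond-level normalisation: the SLS law is used
  exactly as printed for the pair displacement, without the factor 2 that
  a reduced-mass derivation would insert; the KV force, by contrast, acts
  through Newton's third law on both members. The two models therefore
  share a stiffness scale only up to an O(1) factor, which the calibration
  below absorbs.

### The cohesion gradient

The `N−1` bond stiffnesses rise linearly from `k_min` (bond 1) to
`gradient_strength × k_min` (the leading bond). The published model assigns
cohesion per *agent*, but pairwise forces need one stiffness per *bond*;
linear spacing over bonds preserves the linear gradient while keeping
Newton's-third-law pairing unambiguous. The per-agent alternative (each
bond takes its leading member's stiffness) is available as
`bond_gradient = "leading"`.

### Damping

Environmental (Stokes) drag is a retention factor `η_env ∈ [0, 1]` applied
to every velocity after each integration step — `η_env = 0` is the fully
viscous limit, 1 means no drag. The published convention states reductions:
velocities reduced "by 100%" for KV and "by 25%" for SLS, hence the
defaults `η_env = 0` (KV) and `0.75` (SLS). For SLS the per-bond
acceleration memory is damped by the same factor (the source convention
damps velocity *and* acceleration); this is also what keeps the
third-order system stable at `dt = 1`.

### Protrusions

Every `period` timesteps (`T`), each selected cell draws a signed
displacement from a zero-mean Gaussian with standard deviation `amplitude`
(`σ`). The draw is applied instantaneously — protrusion is kinematic
repositioning, not a force — and the displaced cell's velocity (and
adjacent SLS bond memory) is zeroed. A draw that would bring the cell
within one diameter of a neighbour is **rejected outright**: the cell does
not move at all. Rejection, not truncation, is the simulated rule; the
closed-form theory (below) describes the truncated distribution, which is
why its speed prediction is an upper envelope. When several cells protrude
at one event, proposals are drawn for all and validated trailing-to-leading
against already-updated positions, a fixed order that keeps simultaneous
events reproducible.

Modes: `ends_only` (agents 1 and N), `all_cells`, and `hybrid` (ends at
full σ, interior at `interior_scale·σ`, default 0.25 — interior wandering
reduced by 75%).

### Deterministic forcing

The deterministic protocols (fixed-length displacement of the two
outermost cells: repeated outward steps, axial in-phase oscillation, or
toward/away-from-centre oscillation) serve as the null experiment: however
the cluster is periodically deformed, its centre of mass must not drift.
Two design choices follow from demanding that this null be *exact*:

1. Deterministic displacements are imposed without a contact constraint;
   an inward leg that reaches a neighbour produces transient compression
   which the repulsive modulus resolves during relaxation. Any contact
   rule (clipping or rejection) breaks the up/down symmetry of the
   oscillation whenever a bond re-closes between events, and under a
   cohesion gradient this rectifies the forcing into a genuine secular
   drift — precisely the stochastic mechanism, operating where it must
   not. We measured drifts of order 10⁻³ radii/timestep with clipped
   legs; with unconstrained legs the cycle-mean drift is at floating-point
   zero for every submode, model, gradient, amplitude and period.
2. Deterministic events do not reset velocities. Zeroing the velocity of a
   cell that is being pulled back removes momentum asymmetrically (the two
   ends retract at different speeds under a gradient) and biases the COM.

`run_deterministic_baseline()` reports the drift of the COM averaged over
each full forcing cycle; cycle averaging removes the bounded ±2A/N
oscillation that the axial in-phase protocol imposes on the COM, isolating
secular drift. The stochastic protocols keep rejection and velocity reset:
there the contact asymmetry *is* the mechanism under study.

## Closed-form theory

Protrusion lengths follow the half-normal density
`f(x, σ) = 2/(σ√(2π)) · exp(−x²/2σ²)`. With a neighbour at accessible gap
Δ, the mean extension toward it is

`mean(Δ, σ) = √(2/π)·σ · (1 − exp(−Δ²/2σ²)) / erf(Δ/(√2 σ))`,

which tends to Δ/2 for Δ ≪ σ and to the half-normal mean `√(2/π)·σ` for
Δ ≫ σ. (The source text prints the prefactor as "2/π σ"; the radical is
forced by the printed density itself, and the quadrature-equivalence test
pins the implementation to `√(2/π)`.) A cell free on one side and
constrained at Δ on the other gains `⟨disp⟩_Δ = √(2/π)·σ − mean(Δ, σ)` per
event; if the leading cell's gain is transmitted to all `N` masses once
per period, the drift speed is `⟨disp⟩_Δ / (N·T)`. This is the
strong-gradient envelope: it assumes complete re-closure of the leading
bond between events and a fully detached trailing cell, so finite-cohesion
clusters are slower (the reference configuration runs at about 6% of the
envelope). The `1/N` and `1/T` factors, not the prefactor, are its tested
predictions.

## Parameters, defaults, and the stiffness calibration

| parameter | default | meaning |
|---|---|---|
| `n_cells` | 5 | cluster size (3–10 in sweeps) |
| `gradient_strength` | 10 | ratio of strongest to weakest cohesion |
| `k_min` | 0.02 | weakest tensile stiffness (force per unit gap) |
| `kr` | 1 | repulsive stiffness, uniform |
| `zone_max` | 4 | detachment gap, radii |
| `eta_i` | 0.1 | KV bond viscosity |
| `k2`, `tau` | 1, 12 | SLS series spring and relaxation time |
| `eta_env` | 0 (KV) / 0.75 (SLS) | velocity retention per step |
| `amplitude` | 1 | protrusion σ, radii |
| `period` | 15 | steps between events (5 in the speed benchmark) |
| `n_steps` | 2000 | run length |

The source model specifies the *ratios* (gradient strength, damping
reductions) but not the absolute stiffness scale, the repulsion, the SLS
time constant, or `zone_max`. Those were fixed once, by calibrating the
reference configuration (gradient 10, N = 5, σ = 1, T = 5, ends-only,
2000 steps, 100+ replicates) against its reported ensemble speed of
2.0 ± 0.1 mr/τ, under three mechanistic constraints: the leading bond must
re-close substantially within one long period (so the leading cell stays
"closely accompanied"), the trailing bond must not (so the trailing cell
wanders), and no bond may overshoot into deep compression at `dt = 1`.
The creep time `τ = 12` is what separates the short-period regime (little
re-closure in 5 steps, keeping the benchmark speed at ~2 mr/τ) from the
long-period regime (substantial re-closure in 15 steps, which powers the
gradient-, N-, amplitude- and period-sweeps); a purely elastic KV bond
cannot satisfy both at one scale, which is why the SLS variant is the one
that reproduces the reported benchmark speed. KV at the same parameters
produces the same sign, the same nulls, and the same monotone trends
(including the 1/N law), but larger speeds — consistent with the source's
remark that SLS and KV speed values differ because of the extra creep
timescale.

`zone_max = 4` radii is not stated in the source; it is large enough that
bonded neighbours interact across ordinary fluctuations, small enough that
the trailing cell detaches after a few unanswered outward steps.

## Numerical choices

* Classical RK4 on the coupled system, one pass per `dt = 1`, no
  sub-stepping; positions recorded every step. Strong damping and the
  calibrated stiffness scale keep `|λ|dt` well inside the RK4 stability
  region (the stability test runs both rheologies for 2000 steps and
  checks finiteness; a deliberately stiffened configuration must instead
  raise the blow-up error, which reports the offending timestep).
* Non-overlap: accepted protrusions can never create overlap (hard
  rejection, ties accepted at exactly touching). Integration transients
  may compress a bond by up to ~10⁻² radii before repulsion restores it;
  cells are viscoelastic, not rigid, and the trajectory invariant is
  enforced with that tolerance.
* The half-normal closed forms use `expm1` for small-gap accuracy and the
  `erf`–`pnorm` identity; they agree with adaptive quadrature to 10⁻⁸
  relative error over Δ/σ ∈ [0.01, 10] (beyond a few σ the net
  displacement underflows the quadrature error and is compared at the σ
  scale).
* MSD fits are constrained through the origin (the reported regressions
  carry no intercept); R² is computed against the uncentred total sum of
  squares, with the free-intercept R² reported alongside. Because MSD
  values at neighbouring lags are strongly correlated, regression standard
  errors are meaningless for inference; the tests assess the null
  ensemble's quadratic coefficient against a bootstrap over replicates.
* Speed estimates are per-replicate OLS slopes of the COM over the full
  trajectory (no burn-in by default; a `burn_in` argument exists), with
  the standard error of the mean across replicates.
* RNG: R's global generator, seeded once per run; replicate `k` of an
  ensemble uses `base_seed + k`, and sweep cells advance the base seed by
  `n_replicates` so no two replicates share a seed. Identical
  configuration and seed give bit-identical trajectories.

## What the simulations emulate — and what they do not

The generator reproduces the study conditions: 1D geometry, uniform
substrate coupling, a static linear cohesion gradient, instantaneous
protrusion-retraction kinematics, and strong damping. Passing tests
therefore show that the *mechanism* — rectification of unbiased noise by
asymmetric cohesion — is real and quantitatively reproducible in this
idealisation. They do not show that real progenitor clusters are in this
regime: there is no 2D/3D geometry or cell shape, no chemoattractant
consumption or dynamic cadherin regulation, no substrate heterogeneity,
no cell division or death, and protrusions carry no force or persistence.
The gradient enters only as frozen bond stiffnesses, so feedback between
motion and signalling is outside the model.

## Problem sizes

The test suite runs ensembles of 100 replicates (400 for the
interior-migration ordering, whose effect size needs the extra power) of
2000-step, 5-cell simulations, and the N-sweep covers N = 3…10 at 100
replicates for both rheologies; the acceptance script uses 400 replicates
per condition. These match the replicate counts of the reported
experiments (100 per condition) or exceed them where a sharper standard
error is statistically necessary.

## Known limitations

* The theory is an upper envelope with no finite-cohesion correction; the
  package fits no intermediate regime.
* The per-agent ("leading") bond-gradient variant is provided but the
  calibration was performed for the midpoint variant only.
* The axial in-phase deterministic protocol makes the COM oscillate by
  construction; only its cycle-averaged drift is meaningful.
* KV at the calibrated scale reproduces trends, not the absolute benchmark
  speed; quantitative KV work would need its own scale calibration.
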