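---
title: "Methods: bistable population dynamics for distributed analyte detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bistable population dynamics for distributed analyte detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alleeSensor)
```

## The model and its assumptions

A population of engineered sensor cells votes on the presence of a rare
analyte. Each cell is abstracted to two logical states — L (analyte
absent) and H (analyte present) — with densities `L(t)` and `H(t)` in
mL⁻¹. The package works at the mean-field (ODE) level of the underlying
chemical reaction network, under three structural assumptions:

1. **Conserved population.** Replication and death are neglected over the
   experimental horizon, so `L = P − H` exactly and a single state
   variable `H` suffices. All trajectories must stay in `[0, P]`; the
   integrator output is checked against this invariant.
2. **Well-mixed kinetics.** Switching propensities depend only on bulk
   densities: mass action for detection and reset, a Hill function
   `Hⁿ/(Hⁿ + Kⁿ)` for the quorum-sensing-driven positive feedback. The
   Hill form abstracts an AHL/LuxI/LuxR-type circuit: H cells secrete a
   diffusible autoinducer whose receptor complex activates, with
   cooperativity `n`, the promoter that flips L cells to H. The
   mechanistic intracellular species are deliberately not modelled.
3. **Deterministic population, stochastic environment.** The population
   ODE is deterministic; stochasticity enters only through the
   spurious-detection noise process of the robustness experiment (below).

The resulting dynamics for the Allee-based algorithm are

$$\frac{dH}{dt} = \sigma (P-H) + \kappa \frac{H^n}{H^n+K^n}(P-H) - \rho H,$$

with the rare-event detection rate `σ = σ_A·A + σ_err`. Three comparison
algorithms share this state space: *set-reset* (the `κ = 0` nesting, so
the parameter validator deliberately admits `κ = 0`), *broadcasting*
(`dH/dt = σ(P−H) + κ_b H(P−H)`, a bimolecular relay), and *distributed
amplification* (set-reset dynamics for H plus a reporter molecule S with
`dS/dt = κ·Hⁿ/(Hⁿ+Kⁿ)·P − ρS`; secretion is gated by the H density but
performed by all `P` cells).

## Parameters

| parameter | default | units | meaning, and why this default |
|---|---|---|---|
| `kappa` | 35 | h⁻¹ | maximal Hold (feedback) rate; LuxI expression scale from published QS circuits |
| `rho` | 14 | h⁻¹ | Reset rate; LuxI degradation/dilution scale |
| `n` | 4 | — | promoter cooperativity of LuxR–AHL activation |
| `K` | 8·10⁷ | mL⁻¹ | half-activation density of the feedback, a reported high-threshold QS circuit value |
| `P` | 1.5·10⁸ | mL⁻¹ | total density; chosen > 2K and within reachable *E. coli* densities |
| `sigma_A` | 1 | h⁻¹ per analyte unit | detection-rate coefficient; analyte units are arbitrary, so the identity scaling is the neutral choice and the dose axis is then directly a rate axis |
| `sigma_err` | 0 | h⁻¹ | spurious switching; nonzero only in robustness experiments |
| `kappa_bcast` | `kappa / P` | mL h⁻¹ | broadcast relay rate; see below |

The broadcast relay reaction is bimolecular, so its rate constant cannot
share units with `kappa` (h⁻¹). A single published rate value cannot serve
both models; the package therefore defaults to `kappa_bcast = kappa / P`,
which makes the *maximal per-capita* relay rate `kappa_bcast · P` equal to
`kappa` — the two feedbacks are then comparable at saturation. The value
is an explicit, overridable parameter.

`n > 1` is required by the validator: with `n ≤ 1` the feedback
nonlinearity cannot produce the three-equilibrium structure the detector
relies on.

## Equilibrium analysis

Setting `dH/dt = 0` and clearing the Hill denominator in the
dimensionless density `x = H/P` (with `k = K/P`) gives

$$(\sigma(1-x) - \rho x)(x^n + k^n) + \kappa x^n (1-x) = 0,$$

a degree-`n+1` polynomial. For integer `n` its roots are computed via the
companion matrix (`polyroot`), so **no root can be missed** — the property
the critical-rate bisection depends on. Working on the `[0, 1]` scale
keeps the coefficients O(σ+κ+ρ) instead of spanning ~40 orders of
magnitude at density scale 10⁸, and the Hill function itself is always
evaluated as `1/(1 + (K/H)ⁿ)` so that no power of 10⁸ is ever formed.
Numerical choices:

* roots are accepted as real when `|Im| < 10⁻⁶·max(1, |z|)`, kept when
  inside `[0, P]`, and **deduplicated at 10⁻⁶·P**;
* each root is certified by the residual test
  `|dH/dt| ≤ 10⁻⁶·(σ+κ+ρ)·P`; a certification failure raises an error
  rather than returning a doubtful root;
* stability is classified from the *sign* of `dH/dt` at `r ± 10⁻⁵·P`
  (derivative-free, hence robust at near-tangency where the derivative
  itself vanishes); same signs on both sides label the root `tangent`,
  the saddle-node signature;
* for non-integer `n` the solver falls back to an 8192-point sign-change
  scan with `uniroot` refinement; tests cross-check this path against a
  10⁶-point scan.

The feasibility check maximises `g(H) = κ·Hⁿ/(Hⁿ+Kⁿ)(P−H) − ρH` on a
4096-point grid with `optimize` refinement in the bracketing cell; `g`
has at most a few interior extrema for Hill-type shapes, so the coarse
grid cannot skip the global maximum's basin. Bistability of the undriven
system holds iff `g_max > 0`, and then the three `σ = 0` roots
`0 < α_i P < α_f P` define the detection threshold fraction `α_i` and
the detected-state floor `α_f`. Defining `α_i`, `α_f` from the `σ = 0`
root structure is a design choice: it is the definition under which the
memory property ("once above `α_i P`, converge to at least `α_f P`") is
exactly the basin statement of the undriven dynamics, and under which
the undriven threshold coincides with the second-lowest root used by the
convergence-time theory.

## The critical rate

`binary_search_sigma_c()` brackets the saddle-node by the equilibrium
*count*: three roots at `σ = 0` (feasible case), one root at
`σ_utr`, found by doubling upward from `ρ`. Bisection keeps the
three-root side on the left; it terminates when the bracket is narrower
than `precision` (default 10⁻³ h⁻¹, 64-iteration cap) or immediately when
a midpoint exhibits a `tangent` root — the exact-tangency case. With the
default parameters the search gives `σ_c = 3.0552 ± 0.0005 h⁻¹`,
confirmed by an independent dense σ-scan of equilibrium counts
(3 roots at 3.0548, 1 at 3.0550).

A caution from this near-tangency regime: just below `σ_c` the negative
dip of `dH/dt` between the merging equilibria is narrow (at
`σ = 3.04 h⁻¹` it spans only ≈ 2.5% of `P`), so root *counting* based on
coarse sampling of `dH/dt` misses it and biases `σ_c` low by a few
hundredths — which is why the package counts polynomial roots instead of
scanning, and why its tests compare against scans with 10⁵–10⁶ points.

Sweeps over `(κ, ρ)` grids (default 64×64, log-spaced over
`[1, 100] h⁻¹`; ranges configurable) encode infeasible cells as
`σ_c = 0`. Cells are computed in a fixed order with no shared state, so
grids are bit-reproducible.

## Transient simulation

Integration uses `deSolve::lsoda` (stiff-capable, adaptive) with
relative tolerance 10⁻⁸ and absolute tolerance 1 mL⁻¹ against a state
scale of 10⁸ — tight because near-critical transients spend long times
with `|dH/dt|` almost zero, where loose tolerances visibly shift the
crossing times. Output is a dense grid (default 2001 points) used for
interpolated threshold crossings. Piecewise-constant analyte profiles
are integrated segment by segment with the solver restarted at each
discontinuity; adaptive steppers otherwise smooth over jumps. The state
is never forcibly clipped: the right-hand side clamps its *argument*
within solver round-off, and the output is verified to lie within
`[−10⁻⁷P, (1+10⁻⁷)P]`.

Steady states are declared when `|dH/dt| < 10⁻⁶·ρ·P` holds over a
trailing 0.1 h window, with a hard cap of 1000 h (the long-horizon
robustness setting); convergence times are reported as the first
interpolated time `H(t) ≥ 0.95·H_ss`, and 0 for a zero steady state.
Initial conditions default to `H(0) = 0`: all cells start undecided.
Memory experiments integrate through the profile plus a post-removal
window of `10/ρ` (several reset time-constants), and declare the
exposure memorized when the final density is at or above `α_f P`. Since
undriven trajectories approach `α_f P` asymptotically (from below when
started between `α_i P` and `α_f P`), threshold-style assertions in the
tests allow a 10⁻³ relative margin.

## The noise generator

The robustness experiment emulates stochastically fluctuating spurious
detections: an auxiliary species with constant-rate births
(`β = 0.5 h⁻¹`) and per-capita deaths (`γ = 2 h⁻¹`) — leaky-expression
and repressor-decay scales — simulated *exactly* (event-driven Gillespie,
exponential waiting times, base-R Mersenne-Twister with explicit integer
seeds), started at count 0. Its stationary law is Poisson(β/γ = 0.25).
The count drives the detection rate as `σ(t) = sigma_unit · count(t)`
(default `sigma_unit = 1 h⁻¹` per copy, the unit rate constant of the
noise-driven switching reaction), and the population ODE is integrated
deterministically between noise events — a hybrid scheme whose
trajectory is exactly invariant to splitting the noise sequence and
resuming, which the tests assert. The default horizon is 100 h per
replicate with 20 replicates; β/γ excursions large enough to exceed
`σ_c ≈ 3.06` (count ≥ 4, stationary probability ≈ 1.6·10⁻⁴) are both
rare and brief, which is why the detector holds.

What this generator does *not* emulate: intrinsic copy-number noise of
the L/H population itself (the population stays deterministic by
design), cell-to-cell parameter heterogeneity, growth-driven dilution of
the population, or temporal correlation structures other than the
birth–death process's exponential one. A green robustness suite
therefore speaks to environmental false-trigger noise, not to
demographic noise at low cell counts.

## Problem sizes used by the test suite

Deliberate choices, balancing resolution against a desk-scale run: root
oracles use 10⁶-point scans (10⁵ inside σ-scans), oracle-equivalence
checks run 100 random parameter sets with integer `n ∈ [2, 6]`,
the sweep test uses the full 64×64 default grid at precision 10⁻² h⁻¹,
and the robustness ensemble uses 20 seeds × 100 h plus one 10⁴ h run for
the stationary-mean check. The whole suite completes in about a minute.

## Known limitations

* No analytic closed form for `σ_c` is attempted; it is a bisection
  output, and its accuracy is bounded by `precision`, not machine eps.
* Convergence *time* bounds are empirical (95% crossing of the dense
  output); no analytic lower-bound time is computed.
* The dose–response comparison fixes `H(0) = 0, S(0) = 0`; branch
  selection in the bistable window therefore always follows the
  low branch, which is the detection-relevant one.
* Near `σ_c`, steady-state values are ill-conditioned in `σ`
  (critical slowing down); the package reports the integration result
  and the nearest certified root, and the reference table's
  near-critical row is checked against the root, with the wider
  time window.
* `analyte units` are arbitrary; only the product `σ_A · A` matters.
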