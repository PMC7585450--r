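---
title: "Methods: SIS contagion on hypergraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SIS contagion on hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypersis)
```

This vignette documents the models implemented in `hypersis`, the numerical
strategy behind each solver, the design choices that were genuinely open,
and what the package's tests do and do not establish.

## Model

A hypergraph is a set of N nodes plus hyperedges of sizes m = 2, 3, …; a
node's m-th order hyperdegree k⁽ᵐ⁾ counts the size-m hyperedges it belongs
to. We write k for the link degree k⁽²⁾ and q for the triangle degree k⁽³⁾.
Triangles are *not* closed into pairwise links: this is a hypergraph model,
not a simplicial complex.

Dynamics are susceptible–infected–susceptible (SIS), in continuous time:

* every infected node heals at rate γ (1/time);
* a size-2 edge with exactly one infected endpoint infects the other at β₂;
* a size-m hyperedge transmits at βm under one of two rules:
  **collective** — the single susceptible member is infected only when all
  other members are infected; **individual** — every susceptible member with
  at least one infected co-member is infected. For m = 2 the rules coincide;
* with `triangle_sign = "healing"` the size-3 channel is inverted: infected
  members of a qualifying triangle *recover* at β₃ ("hipster effect").

Structure is specified statistically: a degree distribution P(k) plus
connection probabilities. Links follow the configuration-model form
f₂(k,k′) = kk′/(N⟨k⟩). Triangles are either **degree-correlated**,
f₃ ∝ k·k₁·k₂ (nodes with many links sit in many triangles), or
**uncorrelated**, f₃ constant; both are normalised so the mean triangle
degree ⟨q⟩ equals ⟨k⟩. The all-sizes generalisation keeps the
degree-correlated form with one mean hyperdegree ⟨k⁽ᵐ⁾⟩ per size.

## Mean-field reduction

Assuming nodes of equal degree are statistically exchangeable, the infected
fraction x_k per degree class obeys
dx_k/dt = −γx_k + (1−x_k)·n_k, where the class pressure n_k collapses to a
function of one or two order parameters:

| wiring, rule              | n_k |
|---------------------------|-----|
| correlated, collective    | k(β₂V + β₃V²) |
| correlated, individual    | k[(β₂+2β₃)V − β₃V²] |
| uncorrelated, collective  | β₂kV + β₃⟨k⟩U² |
| uncorrelated, individual  | β₂kV + β₃⟨k⟩(2U − U²) |

with V the infected-link fraction and U the prevalence. Healing flips the
sign of every β₃ term. Steady states satisfy x_k = n_k/(γ + n_k) plus the
self-consistency of V (and U); `find_fixed_points()` enumerates them and
`mf_integrate()` integrates the class ODEs (deSolve, `lsoda`, states clamped
to [0,1] against roundoff only).

**Degenerate inputs.** Under healing the net pressure n_k can be negative
and γ + n_k can vanish; the ratio x_k = n_k/(γ+n_k) then leaves [0,1]. The
package takes the physical branch x_k = 0 whenever n_k ≤ 0: with net
negative pressure the clamped per-class dynamics relax to the boundary
equilibrium. This choice only matters for the healing variants and keeps
the residual finite everywhere on the scan grid.

Linearising at the disease-free state gives the thresholds: β₂c = γ⟨k⟩/⟨k²⟩
for collective contagion under either wiring; β₂ + 2β₃ = γ⟨k⟩/⟨k²⟩ for
correlated individual contagion; and for uncorrelated individual contagion a
rational expression whose pole β₃\* = γ⟨k²⟩/[2(⟨k²⟩−⟨k⟩²)⟨k⟩] lies where the
numerator is already negative (not physically relevant; the pole is attached
to the return value as an attribute). For a regular network, where
⟨k²⟩ = ⟨k⟩², the uncorrelated expression collapses onto the correlated one.

## Bistability onset

Above a critical triangle rate β₃c the self-consistency system acquires a
pair of extra roots for β₂ just below β₂c: a stable endemic state coexists
with the stable disease-free state, producing explosive transitions and
hysteresis. Two closed forms complement the numerical search:

* **correlated collective**: the residual's slope at the origin at β₂ = β₂c
  changes sign at β₃c = γ⟨k³⟩⟨k⟩²/⟨k²⟩³ (`beta3c_correlated()`);
* **uncorrelated collective**: eliminating U to second order in V and
  expanding the V-residual to fourth order at β₂ = β₂c gives
  h(V) = (a₀ + a₁V + a₂V²)V², with (b = β₃/γ)

  a₀ = ⟨k⟩(⟨k⟩⁴b − ⟨k³⟩)/⟨k²⟩²,

  a₁ = ⟨k⟩²(2⟨k⟩⁶b² − 4⟨k⟩³⟨k²⟩b + ⟨k⁴⟩)/⟨k²⟩³,

  a₂ = ⟨k⟩³(⟨k⟩⁸b³ − ⟨k⟩⁷b² − 6⟨k⟩⁵⟨k²⟩b² + 3⟨k⟩³⟨k³⟩b + 5⟨k⟩²⟨k²⟩²b −
  ⟨k⁵⟩)/⟨k²⟩⁴.

  These expressions were re-derived symbolically (computer algebra) rather
  than transcribed, because the typeset grouping of the higher coefficients
  is ambiguous in circulation; equivalent quartics differing by multiples of
  a₀ exist, and the derivation here fixes one consistently. Two anchor
  identities pin it down: a₀ = 0 exactly at β₃ = γ⟨k³⟩/⟨k⟩⁴ (the
  transcritical onset), and at β₃ = 0, a₀ = −⟨k⟩⟨k³⟩/⟨k²⟩² < 0 (no
  bistability without triangles). The onset is the smallest admissible root
  of the saddle-node condition a₁² − 4a₀a₂ = 0 (requiring a₂ < 0 and vertex
  −a₁/2a₂ ∈ [0,1]), else the transcritical value; for a regular network the
  saddle-node root is inadmissible (vertex ≈ 3.4) and the transcritical
  branch gives β₃c/β₂c = 1. Because U is truncated at second order, a₂ omits
  third-order feedback; the formula's error relative to the numerical onset
  grows with degree heterogeneity (about 10% for the exponent-4 power law),
  while a₀ and a₁ are exact at their order — the tests verify both against a
  numerical Taylor fit of the reduced residual. Extending the expansion
  beyond fourth order is out of scope: the admissibility bookkeeping grows
  much faster than the accuracy.

`beta3c_numeric()` locates the onset without expansion: bisection on β₃
(relative width 1e-4 by default) of the predicate "some β₂ in the
multiplicity grid yields three steady states".

## Numerical choices

* **Root scan.** V is scanned on a uniform 2001-point grid on [0,1]
  *augmented with a geometric refinement* (200 points, 1e-7…1e-3) near V = 0,
  because at onset the extra root pair is born at V → 0 and a uniform grid
  misses it. Brackets are polished by bisection to 1e-12; roots closer than
  1e-6 in V are merged (separates genuine saddle-node pairs near onset while
  absorbing polish noise). A residual exactly zero on a grid point is taken
  as a root directly. Phase-diagram counting uses a 1001-point scan:
  coarsening can merge sign changes but never create them, so
  absence-of-bistability conclusions are unaffected.
* **Multiplicity β₂ grid.** The extra solutions appear for β₂ just below
  β₂c, and the detectable onset shift scales like the square root of the
  closest grid point's relative distance to β₂c. The grid therefore clusters
  geometrically toward β₂c down to relative distance 1e-9 (onset bias
  ~1e-4), with a coarse tail over [0.5, 0.9]·β₂c and two points above β₂c.
* **U elimination (uncorrelated wiring).** At each V the U equation is
  solved by fixed-point iteration warm-started from the previous grid point
  (plain iteration, with damped retries ω = 0.4, 0.16 if it cycles;
  tolerance 1e-13). In the regimes explored the map is a contraction;
  non-convergence yields NaN, which the scanner skips and reports.
* **Stability labels.** Interior roots by the sign of the reduced residual's
  slope (negative = stable); the disease-free root by the linearisation of
  the dynamics (the 2×2 system in (U,V) for uncorrelated individual
  contagion). The test suite cross-validates labels by integrating the class
  ODEs from ±1e-4 perturbations of each root.
* **Phase-diagram ranges.** Defaults of 0–2β₂c × 0–3β₃c cover the three
  regimes of the contagion models. For individual contagion with
  higher-order healing the instability line is shifted to β₂ ≈ β₂c + 2β₃ and
  the narrow bistable band sits near it (around β₂ ∈ [6, 8]·β₂c for the
  exponent-4 power law), so the defaults widen to 0–10β₂c × 0–5β₂c there.

## Hypergraph generation

`sample_links()` fixes the link count at round(N⟨k⟩/2) and draws endpoint
pairs proportional to degree by inverse-CDF lookup, matching
f₂ = kk′/(N⟨k⟩) in expectation without the multi-edge cleanup of stub
matching distorting P(k); classical stub matching (exact degree sequence,
self-loops repaired by degree-preserving swaps) is available as an option.
`sample_triangles()` draws round(N⟨q⟩/3) member triples proportional to
degree (correlated) or uniformly (uncorrelated), distinct members within a
hyperedge, duplicates across hyperedges retained — each duplicate is an
independent contagion channel, which keeps the per-hyperedge rate semantics
exact. `sample_hyperedges()` generalises the correlated rule to any sizes.
All sampling flows from one seed.

What the generator emulates: the wiring statistics (f₂, f₃ and the size-m
generalisation) of the mean-field theory, hence degree heterogeneity and
link–triangle degree correlation. What it does not: triadic closure or any
clustering beyond the prescribed forms, degree–degree assortativity,
community structure, temporal contact patterns. Passing tests therefore
validate the theory *under its own structural null model*, not on real
contact data.

## Stochastic simulator

`simulate_sis()` is a statistically exact Gillespie scheme. Each hyperedge
class keeps an integer weight per edge — the number of eligible targets
under its rule (1 for a collective-ready edge, m − cnt for an individual
edge with cnt ≥ 1 infected, …) — plus an active-edge list and an exact
integer total weight, so channel rates are βm·Wm with no floating-point
drift. Events are drawn by inversion over channels, then rejection on
weight within the active list; state flips update only the flipped node's
incident edges. The engine uses R's RNG, so a single `set.seed()` makes
entire sweeps bit-reproducible, and rescaling all rates by c rescales every
event time by 1/c with an identical event sequence (a property the tests
assert exactly). γ = 0 is accepted — the pure-infection chain is what the
exponential waiting-time exactness tests probe.

`hysteresis_sweep()` implements the adiabatic protocol: β₂ stepped up then
down (default 40 steps per branch over [0.5, 1.5]·β₂c), each step discarding
a transient (default 10/γ) and averaging prevalence over a window (default
30/γ), carrying the final microscopic state between steps. If the chain hits
the absorbing disease-free state on the *up* branch it is re-seeded with
0.5% infected (logged); without this, escape from the absorbing state is
impossible and the up branch would be identically zero. These defaults are
this package's own protocol choices; they resolve the branch structure at
N = 10³–10⁴ with ⟨k⟩ = ⟨q⟩ = 100 and are all overridable.

The mean-field theory is *not* quantitatively exact against the simulator —
the closure ignores dynamical correlations between neighbours, and the
simulated transition points sit visibly away from the mean-field ones on
heterogeneous hypergraphs. Agreement is asserted quantitatively only on the
regular links-only graph (where the closure is accurate; quasi-stationary
prevalence within 0.02 of 1 − γ/(β₂k) at N = 2000), and qualitatively
elsewhere (presence/absence of hysteresis, ordering of jump locations).
Near onset the simulated bistability index is noisy: finite-size
fluctuations let the chain jump between basins, which is why the
simulation-side checks use a noise floor (gap < 0.12 counts as "no
hysteresis", > 0.2 as hysteresis, calibrated on the N = 10³ fixture).

## Problem sizes used by the tests

Unit tests run on small systems (N ≤ 2000, reduced grids) chosen so the
whole suite completes in minutes at one CPU; the end-to-end checks use the
calibrated distributions (uniform on 51..149, power laws with exponents 4
and 3 on 67..1000 and 53..1000, all mean degree ≈ 100, γ = 2), 101×101
phase diagrams, and sweeps on the N = 10³ fixture. The full-size N = 10⁴
sweep is a demo (`demo("full_sweep")`), not a test: at that scale only
qualitative reproduction is expected, and it is too slow for routine runs.

## Limitations

* Mean-field closure only; no pair approximation or correlated-pairs
  correction, so simulated curves are matched qualitatively.
* Connection probabilities depend on degrees alone; no assortativity by
  other node attributes, no estimation of f_m from data.
* Markovian dynamics only; no quorum (j-of-m) contagion rule.
* The q-resolved formulation (triangle-degree-specified wiring) is a
  symmetric relabelling of the implemented machinery and is not separately
  exposed.
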