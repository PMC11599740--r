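---
title: "Qualitative dynamics of the HIF-1 regulatory network: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative dynamics of the HIF-1 regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qualdyn)
```

## The modelling framework

`qualdyn` implements kinetic logic in the Thomas tradition. An entity's
discrete level abstracts its expression; an interaction's threshold marks
the level at which a regulator starts to act; the logical parameter
`K_v(ω)` is the level entity `v` is attracted toward when exactly the
resource subset `ω` of its regulators is acting. Resources encode the
biological asymmetry between activation and inhibition: an activator
counts when present (at or above threshold), an inhibitor counts when
*absent*. Dynamics are asynchronous and unitary — one entity moves one
level toward its target per transition — which is the conservative reading
of stepwise expression change; for Boolean models unitary and
jump-to-target semantics coincide, so the choice only matters for
user-supplied multilevel models.

Three structural conventions are fixed package-wide:

* **Entity order is explicit and user-given.** It defines the coordinate
  order of every state vector and the digit-string serialization
  (`"111110111"`), and is stored in every model file (`entity_order`).
* **Levels are user-declared**, not derived from out-degree. The classical
  presentation ties the maximal level to the number of distinct targets,
  but curated Boolean models (including the packaged one, where entities
  with two or three targets are still Boolean) do not follow that rule, so
  `max_level` is an explicit field.
* **At most one interaction per ordered pair**, since a single
  (sign, threshold) pair is attached to each edge.

Entities with no regulators hold a constant target `K(∅)`; the packaged
network has none, so this only affects user models.

## CTL checking and the deadlock convention

Observations are written in CTL and evaluated by fixpoint labelling
(`EX` by preimage, `EF`/`EU` as least fixpoints, `EG` as a greatest
fixpoint, universal quantifiers by duality). CTL semantics needs a total
transition relation, so fixed points receive an implicit self-loop. This
is not a technicality: it is what makes `EF(AG(pattern))` — "the system
can enter the pattern and stay there" — true *at* a stable state carrying
the pattern, which is exactly how the packaged observation formulas
describe the pathogenic and homeostatic fates. The convention is applied
uniformly across all operators, and the checker is cross-validated in the
test suite against a brute-force path/lasso oracle on hundreds of random
formulas over small graphs.

The default `holds` mode is `all_states`: the packaged observations are
implications, vacuously true outside their antecedent pattern, which is
the standard convention for parameter identification. The mode is
configurable.

## Parameter identification and the search frame

The raw space of complete K tables for the packaged network is
`∏_v 2^(2^|regulators(v)|) ≈ 10^9`, far beyond exhaustive checking at a
desk. `enumerate_parameters()` therefore fixes individual K entries before
enumerating, from three sources:

1. **Sound propagation from the observations.** For a conjunct
   `p ⇒ EF(AG(q))` with satisfiable atom-conjunctions `p` and `q`, the
   `q`-region must contain a trap. Any entity constrained by `q` whose
   regulators are *all* constrained by `q` has a constant resource set
   across the region, and its K there must equal its `q`-level — otherwise
   every `q`-state exits the region and the formula is unsatisfiable.
   This fixes the p53, AKT and OGT entries of the case study (six
   entries), and is verified in the tests to leave catalogs unchanged
   relative to naive enumeration.
2. **Steady-state anchors** (`anchor_steady`): requiring a state to be a
   fixed point fixes one entry per entity.
3. **Walk anchors** (`anchor_walk`): requiring a printed trajectory or
   cycle to be edge-valid fixes the stepping entity's entry at each step.

Anchors 2–3 are search-frame restrictions, not consequences of the
observations, and the package is explicit about this: they encode the
published stable state and the published cycle as part of the reproduction
target. Within that frame the case study leaves 4096 candidate tables;
each is checked in full (state graph + CTL), and 795 satisfy the three
observations. Every surviving candidate — with no exception across the
whole catalog — has `K_HIF-1({ERK}) = 1`: ERK-driven HIF-1 induction is
forced by the observations, reproducing the headline constancy claim.
Catalog order is deterministic (lexicographic over the flattened K
vector), so `M1 … Mn` labels are stable across runs but intentionally
package-specific.

## Why the packaged model has two stable states

The second observation formula demands that the homeostatic freeze
(VEGF, OGT, GLUT-1, HIF-1 off; AKT on; p53 off) can become permanent. Once
those six entities are frozen, the three free entities (ERK, β-catenin,
C-MYC) have no feedback among themselves in this network — ERK's only
regulator is VEGF, β-catenin's is AKT, and C-MYC's regulators β-catenin
and OGT cannot oscillate — so any permanent homeostatic region settles
into a genuine fixed point. Consequently *every* parameter set satisfying
the observations has (at least) two fixed points, and the members whose
fixed points are *exactly* the two printed stable states — the pathogenic
deadlock `(1,1,1,1,1,0,1,1,1)` and the recovery state
`(0,0,0,0,0,1,0,0,0)` — are the faithful reading of the published
analysis, which describes a pathogenic deadlock *and* a stable recovery
state. The packaged model is selected deterministically from the catalog:
fixed points exactly {deadlock, recovery}, the printed 12-state cycle
edge-valid, and, among the 175 qualifying members, the fewest Snoussi
monotonicity violations. That minimum is exactly one violation — AKT's
`K(∅) = 1 > K({VEGF}) = 0` — and it is irreducible: the two printed
stable states force AKT's K entries to invert its declared activation by
VEGF. This is also why Snoussi and observability constraints are **off by
default** in validation and enumeration: the published fixtures are
inconsistent with them, so they are offered as optional filters (and power
the property tests) rather than imposed.

`fixed_points()` reports what the scan finds — both states. The
package deliberately does not suppress the recovery fixed point to match
the phrase "a single deadlock state"; it reads that phrase as "a single
*pathogenic* stable state", which the model reproduces.

## Graph analysis choices

Betweenness is directed, unweighted, unnormalized, with endpoints
excluded — the definition's literal form; rankings are invariant to the
constant normalization factor. Ranking ties break lexicographically on
the state label so output is stable. Cycle extraction enumerates simple
cycles inside non-trivial strongly connected components with an explicit
cap (default `1e5` cycles) because "the cycle with the highest
centrality" is not otherwise well-defined; cycles are scored by mean
member betweenness (min and sum are available), ties prefer longer
cycles, then the lexicographically smallest starting state. Path
extraction restricts to shortest paths first and then maximizes mean
intermediate betweenness by dynamic programming over the BFS layer DAG;
unrestricted maximum-betweenness paths are ill-posed (they can wander
indefinitely).

A *bifurcation state* is a non-attractor state with at least two
successors whose reachable-attractor sets differ. On the packaged model
this strict reading yields 96 states and includes three of the seven
published decision points; the other four branch only further downstream
(all their immediate successors still reach both fates). The biological
content of the published list — both the deadlock and the recovery
attractor remain reachable from each printed state — is checked as such
in the reproduction report and the acceptance tests. Similarly, the
published claim that the cycle states dominate the centrality ranking is
not reproducible under the literal betweenness definition (the packaged
cycle's states rank between 28 and 483 of 512); since the published
ranking procedure is not specified beyond the formula, the package makes
no such claim.

Attractor labels: an attractor is "recovery" when all of its states
satisfy the homeostatic labels (the second observation formula); without
a formula, cyclic attractors are treated as recovery (sustained
oscillation being the generic signature of homeostasis). Fixed points not
labelled recovery are "deadlock".

## The continuous translation

`brn_to_ode()` produces `dx_v/dt = β_v f_v(x) − γ_v x_v` with
`f_v ∈ [0,1]`. The default regulation function is the **multilinear
interpolation of the logical K table**: each regulator contributes a
continuous resource weight (Hill `H(x; θ, h)` for activators, `1 − H` for
inhibitors), and `f_v` is the expectation of `K_v/ℓ_v` over resource
subsets under those weights. With steep Hill functions this makes the
continuous steady states mirror the logical stable states, which is the
property the co-simulation stage exists to exercise. A signs-only product
form (`regulation = "product"`) is also provided, but it cannot express
the packaged model's AKT logic (VEGF is AKT's only regulator and is
declared an activator, yet AKT must be low in the pathogenic state and
high in recovery), so it is not the default.

Kinetic units are abstract: β in concentration/time, γ in 1/time, θ in
concentration at half-activation, h dimensionless; concentrations are
reported as mM/L by convention. The packaged scenarios use θ = 0.5 and
h = 8 (h = 3 in the hyperactivation scenario, where a shallower response
keeps sensitivities well away from saturation), with β/γ calibrated only
to the qualitative narrative: `pathogenic` and `recovery` reproduce the
two logical stable patterns when the equilibrium is thresholded at θ;
`demo_b` gives faster VEGF clearance than ERK degradation; `demo_c` gives
a positive equilibrium sensitivity of GLUT-1 to ERK production; `demo_d`
is an inhibition scenario used for the equilibrium contract. The original
study's printed concentrations (its supplementary rate equations are not
public) are **not** reproduction targets; only these qualitative
properties are.

Numerics: integration uses lsoda (adaptive, stiff-capable); trajectories
are clipped at zero within solver tolerance; equilibria are found by a
500-time-unit approach integration followed by damped Newton refinement
with a finite-difference Jacobian to residual `≤ tol` (default `1e-8`);
sensitivities are central log-elasticities `d ln y / d ln p` at ±5%
perturbation, which gives exactly ±1 for the unregulated-species
closed form `x* = β/γ`.

## The synthetic generators

`random_network()` emulates the structural class of curated signalling
models: signed thresholded digraphs where every entity is regulated (a
self-input of random sign is added where sampling leaves none, and
flagged). `random_parameters()` samples complete K tables uniformly, or
by monotone completion when Snoussi-consistent tables are required;
`random_network_no_positive_circuit()` rejection-samples on circuit signs
to drive the multistationarity property test (no positive circuit plus
Snoussi monotonicity implies at most one fixed point). All generators are
integer-seeded and platform-deterministic. What they do *not* emulate:
realistic degree distributions, hub structure, or biologically calibrated
thresholds — passing property tests on generated instances demonstrates
algorithmic correctness on the structural class, not biological fidelity
on real pathways.

Problem sizes in the default test run were chosen to keep the whole suite
near twenty seconds while preserving statistical force: the CTL checker
is cross-checked against the brute-force oracle on 200 random formulas of
depth ≤ 4 over graphs of ≤ 16 states; betweenness against exhaustive
shortest-path enumeration on 100 digraphs of ≤ 12 nodes; the
multistationarity rule on 100 four-entity instances; pipeline smoke
coverage on 20 sixteen-state models.

## Known limitations

* The published interaction figure's edge list is reconstructed from the
  surrounding text; an alternative reading ships as `hif1_alt.json`, and
  claims conditioned on the reconstruction (catalog size in particular)
  are frame-relative. The published count of eight parameter sets is not
  recovered (the constrained frame yields 795), and nothing in the public
  record pins down the constraints that would reduce it.
* State-space enumeration is explicit, with a configurable cap (default
  `1e6` states); there is no symbolic (BDD) representation, so very large
  multilevel models are out of reach.
* Synchronous and priority-class update schemes, CTL*/LTL, fairness, and
  witness extraction are out of scope; reachability paths come from the
  centrality machinery instead.
* The ODE stage is a generic translation for qualitative concordance, not
  a fitted kinetic model; its outputs are patterns and signs, not
  concentrations to be believed numerically.
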