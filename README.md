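# qualdyn — qualitative dynamics of biological regulatory networks

`qualdyn` analyses gene/protein regulatory networks with René Thomas'
kinetic-logic formalism and packages a complete worked case study: the
HIF-1/VEGF/GLUT-1 signalling network that drives glucose uptake and
angiogenesis in cancer. It is written for systems biologists who want to go
from a signed interaction diagram and a handful of qualitative observations
to attractors, decision points and testable trajectories — without rate
constants.

## The formalism

A **biological regulatory network** is a directed graph over entities
`v ∈ V`, each with a discrete expression range `{0, …, ℓ_v}` (Boolean in the
case study). Each interaction `u → v` carries a sign (`+` activation, `−`
inhibition) and a threshold `τ`. In a qualitative state
`E = (e_1, …, e_n)`, the **resources** of `v` are the regulators currently
acting on it:

    R_v(E) = { u : (σ(u,v) = + and e_u ≥ τ) or (σ(u,v) = − and e_u < τ) }

— an above-threshold activator, or an *absent* inhibitor. A complete table
of **logical parameters** `K_v(ω)` gives the level `v` is attracted toward
for every resource subset `ω ⊆ G⁻(v)`. Asynchronous unitary dynamics move
one entity one level toward its target per transition; the resulting
**state transition graph** over all `∏(ℓ_v + 1)` states is the object every
downstream stage works on:

* **CTL model checking** (`parse_ctl()`, `ctl_satisfy()`, `ctl_holds()`):
  observed behaviours written in computation tree logic (`EF`, `AG`,
  `E[· U ·]`, …) are evaluated by fixpoint labelling; fixed points get an
  implicit self-loop so the transition relation is total.
* **Parameter identification** (`enumerate_parameters()`,
  `select_model()`): exhaustive search over complete K tables, pruned by
  entries the observation formulas provably force, keeping the tables whose
  state graph satisfies the observations.
* **Graph analysis** (`state_betweenness()`, `max_centrality_cycle()`,
  `max_centrality_path()`, `bifurcation_states()`): states are ranked by
  directed, unnormalized betweenness centrality
  `BC(e) = Σ_{s≠t≠e} σ_st(e)/σ_st`, and high-centrality cycles and
  shortest paths pick out the trajectories that matter.
* **Attractors** (`attractors()`, `label_attractors()`): terminal strongly
  connected components, labelled pathogenic deadlock or homeostatic
  recovery.
* **ODE co-simulation** (`brn_to_ode()`, `simulate_ode()`,
  `ode_equilibrium()`, `ode_sensitivity()`): a Hill-kinetics continuous
  translation `dx_v/dt = β_v f_v(x) − γ_v x_v`, where `f_v` interpolates
  the logical K table multilinearly, so discrete stable states and
  continuous equilibria can be compared.
* **Synthetic generators** (`random_network()`, `random_parameters()`,
  `random_kinetics()`): seeded instances with the structural properties
  the analysis assumes, used throughout the property-based tests.

## Worked example: the HIF-1 case study

```r
library(qualdyn)

model <- hif1_model()          # 9 entities, 14 interactions, packaged K table
g     <- state_graph(model)    # 512 states, 2304 transitions

fixed_points(g)$state
#> [1] "000001000" "111110111"
```

The two stable states are the printed recovery state (everything off, AKT
on) and the pathogenic deadlock (everything on, AKT off). All three
packaged observation formulas hold on the model:

```r
sapply(hif1_ctl(model$network), function(f) ctl_holds(g, f))
#> [1] TRUE TRUE TRUE

at <- label_attractors(g, recovery_formula =
        "VEGF=0 & OGT=0 & GLUT1=0 & HIF-1=0 & AKT=1 & P53=0")
at$attractors[, c("kind", "size", "label")]
#> 1 fixed_point     1 recovery
#> 2 fixed_point     1 deadlock
```

Betweenness centrality ranks the 512 states and extracts the
highest-centrality route from the published trajectory source into the
deadlock; every intermediate state is still a decision point
(`bifurcation`: both fates reachable) until the final commitment:

```r
cm <- state_betweenness(g)
tr <- max_centrality_path(g, hif1_fixtures()$trajectory_source,
                          hif1_fixtures()$deadlock, centrality = cm, atts = at)
tidy(tr)
#>    step state     betweenness classification
#> 1     1 101111001          0  bifurcation
#> 2     2 101111011       4359. bifurcation
#> 3     3 101111111      13385. bifurcation
#> 4     4 101110111       7003. bifurcation
#> 5     5 111110111          0  toward_deadlock
```

`reproduce_hif1("report/")` re-runs the whole pipeline (state graph, fixed
points, observation formulas, printed 12-state cycle, bifurcation
reachability, centrality export) and writes a deterministic
machine-readable report; all 20 claims pass on the packaged model.

The continuous stage mirrors the discrete one: with the packaged
`"pathogenic"` kinetics the ODE equilibrium, thresholded at each species'
Hill threshold, reproduces the deadlock pattern `111110111`; with the
`"recovery"` kinetics it reproduces `000001000`.

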