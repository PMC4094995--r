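---
title: "LP-based gap-filling of metabolic networks: methods and design notes"
author: "fastgapfill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{LP-based gap-filling of metabolic networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastgapfill)
```

## The problem

Flux balance analysis (FBA) models the steady-state fluxes `v` of a
metabolic network through the linear program

    maximize   f_b            (biomass flux, the growth proxy)
    subject to S v = 0        (no net production of any internal metabolite)
               0 <= v <= u    (flux bounds, mmol/g/h)

where `S` is the stoichiometric matrix. A reconstructed network is often
*incomplete*: the biomass reaction cannot carry flux because some
biosynthesis step is missing, so the model predicts no growth.
*Gap-filling* proposes reactions from a candidate pool `M` (typically a
reaction database, thousands of entries) whose addition restores growth.

The classical formulation attaches a binary inclusion variable to each
candidate and asks a MILP solver for the minimum-cost inclusion set. That
is exact but can be extremely slow at database scale. The method
implemented here replaces the MILP by a short sequence of plain LPs.

## The algorithm

All candidates are added to the LP at once, penalized in the objective by
their per-flux costs `c_r`:

    maximize  delta * f_b  -  sum over r in M of  c_r * f_r

subject to the same steady-state and bound constraints, over the union of
model reactions `N` (objective coefficient 0), candidates `M` and
exchanges. For small `delta` the penalty dominates and nothing moves; for
large `delta` growth dominates and many candidates activate. The driver
(`fast_gap_filling()`):

1. probes `delta = |M|`; if the optimum has no growth the instance is
   declared infeasible at this weighting (the method's known shortcoming:
   it cannot complete the network when no candidate subset can produce the
   *entire* biomass metabolite set — the advice attached to the result is
   to reduce the biomass reaction's metabolite set);
2. binary-searches `delta` over `(0, |M|]`: any growth-positive optimum
   records the active candidate set `{r : f_r > eps_active}` and lowers
   the upper bracket endpoint; no growth raises the lower endpoint;
3. stops when the bracket is narrower than 1, so at most
   `ceiling(log2 |M|) + 1` LPs are solved (`iteration_count()`).

The recorded sets are deduplicated and reported smallest-first. The
heuristic *tends* to shrink the suggested set as `delta` decreases but
carries no optimality guarantee; `milp_gap_fill()` provides the exact
minimum for cross-checks on small instances.

Only the biomass objective coefficient changes between iterations, so the
constraint matrix is assembled and presolved once per run.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eps_growth` | 1e-6 | biomass flux above this counts as growth; "non-zero flux" needs a numerical threshold |
| `eps_active` | 1e-8 | candidate flux above this counts as active |
| flux cap | 1e6 mmol/g/h | stands in for an unbounded flux so every LP stays bounded and ineffective high fluxes are excluded |
| `eps_balance` | 1e-6 | tolerated steady-state residual, matching double-precision LP arithmetic |
| `flux_ratio_threshold` | 0.01 | pruning: a candidate below 1% of the solution's top flux is tentatively dropped |

Costs express the plausibility of a candidate for the organism; only their
relative magnitudes matter. The default scheme is 1 for a spontaneous
(non-enzymatic) reaction, 5 / 10 / 15 for enzymatic reactions inside /
of unknown relation to / outside the organism's taxonomic range, and a
biomass gain of 500 per metabolite (used only by the soft-biomass MILP
variant) — a gain-to-in-range-cost ratio of 100.

```{r costs}
s <- default_cost_scheme()
unlist(s)
s$biomass_gain / s$in_range_cost
```

A practical consequence of the parametric objective: a completion whose
cost-per-unit-of-biomass exceeds `|M|` can never activate, because
`delta` never exceeds `|M|`. The method's native regime is a candidate
pool several orders larger than any single completion's cost, which is
exactly the database-scale setting it was designed for. The synthetic
benchmarks pad pools with decoys for this reason, not only for realism.

## Preprocessing

*Reversible splitting.* Every reversible reaction becomes two opposed
irreversible reactions (`_fwd`/`_rev`), so all fluxes are non-negative.
The reverse direction takes bounds `[0, -lb]` when `lb < 0`, else
`[0, ub]`. A split *candidate* inherits the full parent cost in both
directions — either direction must be selectable on its own, and the
gap-filler can then report the biologically relevant direction as part of
the solution. Equivalence of the split and free-sign formulations is
property-tested against an independent LP solver.

*Generic-reaction instantiation.* Reactions written over compound classes
expand against a user-supplied class map. Distinct classes expand by
Cartesian product. Where a chemically coupled family must move in
lockstep (a class and, say, its phosphorylated counterparts), the class
map declares the pairing explicitly (`paired_with`), and paired classes
substitute member `i` with member `i`. An explicit declaration was chosen
over inferring pairings from id prefixes: id conventions differ across
databases, and a silent wrong pairing would produce chemically absurd
reactions. A class with no members drops the reaction with a warning
diagnostic rather than an error, since a database pool routinely contains
classes outside the model's compound set.

*Growth environment.* Uptake exchanges (`EX_<id>_in`, bounded by the
nutrient's uptake cap) and export exchanges (`EX_<id>_out`) are attached
once, idempotently. The gap-filler itself never touches the environment:
nutrients and secretions are assumed correct before completion is
attempted.

## Numerical choices

The LPs are solved by an in-package bounded-variable primal revised
simplex (C++): every program here has right-hand side zero and finite
upper bounds, so the zero flux vector is a basic feasible starting point,
no phase-1 is needed, and unboundedness is impossible. Dantzig pricing is
used with a permanent switch to Bland's rule after a long degenerate
stall (flux LPs at the zero vertex are heavily degenerate), which
guarantees termination; the basis inverse is maintained by eta updates
and refactorized periodically and before solution extraction.

A presolve removes reactions that can never carry steady-state flux
(iteratively: a metabolite with no producer forces its consumers to zero
and vice versa). This is exact — the removed fluxes are zero in every
feasible point — and it shrinks database-scale pools to the connected
core, which is what makes 5,000-candidate instances cheap.

Degenerate optima are possible: alternative candidate sets can achieve
the same objective, and the reported active set is whichever vertex the
solver returns. The exact filler has the same property (only one optimal
inclusion set is returned). Determinism is still guaranteed for fixed
inputs, and the output ordering (size, then cost, then ids) is a stable
tie-break.

Strictly positive flux lower bounds (e.g. ATP maintenance constraints)
are not supported: they would make the zero vector infeasible and require
a phase-1 start. Models using them must encode the requirement
differently (e.g. as a biomass component).

## The exact oracle

`milp_gap_fill()` solves the minimum-cost formulation — binary inclusion
variables `y_r`, big-M linking `f_r <= 1e6 * y_r`, hard growth constraint
— by exhaustive branch and bound: a node excludes a candidate (bound
drops to zero) or commits to it (cost charged); an LP maximizing biomass
over the still-allowed candidates prunes infeasible nodes, and committed
cost prunes nodes that cannot beat the incumbent. Every incumbent is
confirmed by an FBA re-solve before acceptance. The hard-biomass
formulation was chosen over the soft variant (each biomass metabolite
worth `biomass_gain` when producible) because the heuristic it is
compared against treats the full biomass as fixed; the soft variant is
documented but off by default. Exactness is tested against cost-ordered
exhaustive subset enumeration for pools of up to 12 candidates.

## What the synthetic benchmarks emulate — and what they do not

`make_chain_model()` builds seeded linear/branched biosynthesis pathways
(one nutrient, a chain of essential steps, one branch per biomass
precursor, coefficients in {1, 2}); `knockout()` removes reactions and
*asserts* that growth is prohibited; `add_decoys()` pads the pool with
mass-disconnected reactions (touching fresh dead-end metabolites) with
randomized kinds and taxonomic statuses. Every generated instance
therefore satisfies three guarantees: the complete model grows, the
incomplete one does not, and the knocked-out set is a completion.

Decoys are deliberately disconnected. This emulates the dominant feature
of a real database pool — the overwhelming majority of its reactions
cannot carry steady-state flux in a given small model — and it keeps the
minimal completion of a chain instance unique, which is what lets the
tests compare the heuristic against the exact filler set-for-set. What
the generator does *not* emulate: genome-scale topology (cofactor
coupling, parallel pathways, loops), alternative completions from within
the database, and compartmentalization. Passing the benchmark suite
therefore demonstrates algorithmic correctness (soundness of every
returned set, the iteration bound, exactness of the oracle, directional
recovery), not biological performance on curated genome-scale models.

Test problem sizes: the benchmark sweep uses 50 instances of 16
metabolites with 1–14 knockouts and pools of 3 to 5,000 candidates;
oracle comparisons use pools of at most 12 candidates for exhaustive
ground truth. These sizes exercise every code path (including the
database-scale presolve) while keeping a full run in the order of
seconds.

## Known limitations

- No solution is found when no candidate subset produces the entire
  biomass metabolite set; the tool then recommends reducing the biomass
  reaction rather than silently relaxing it.
- Completions costlier than `|M|` per unit biomass are invisible to the
  search (see above); enlarge the pool or lower costs if this regime is
  suspected.
- The heuristic may return supersets of the minimum (one extra low-flux
  reaction is the characteristic case); `prune_low_flux()` removes such
  riders when they are truly non-essential, by construction never
  returning an unverified set.
- Compartments are carried but not interpreted; transport modeling,
  gene-protein-reaction rules and thermodynamic constraints are out of
  scope.

## A worked example

```{r example}
inst <- make_instance(n_metabolites = 10, biomass_size = 2,
                      n_knockouts = 4, n_decoys = 30, seed = 11)
inst$knocked_out
sols <- fast_gap_filling(inst$model, inst$pool)
attr(sols, "lp_solves")
sols[[1]]
verify_solution(inst$model, inst$pool, sols[[1]])
milp <- milp_gap_fill(inst$model, inst$pool)
identical(sols[[1]]$active_set, milp$active_set)
```
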