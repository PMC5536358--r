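---
title: "Flux-balance screening of gene dysregulation: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux-balance screening of gene dysregulation: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepaflux)
```

## The model and its assumptions

`hepaflux` treats metabolism as a steady-state stoichiometric system. Every
reaction is split into non-negative forward and backward flux columns, so a
reversible reaction with bounds (lb, ub) becomes a forward column on
(max(lb,0), max(ub,0)) and a backward column on (max(−ub,0), max(−lb,0)),
and mass balance reads **N**(v_f − v_b) = 0. The assumptions inherited from
flux balance analysis apply: no metabolite accumulation or dilution, a
single cellular objective, and constraints expressed entirely as bounds and
fixed fluxes. The objective here is maximal ATP production through a demand
reaction for cytosolic ATP; if a model declares a metabolite objective
without such a demand, one is appended automatically (`DM_<metabolite>`),
flagged as an exchange so it never enters the flux-norm sum. An explicit
objective reaction can be declared instead. Biomass objectives are out of
scope: the intended substrate models carry a blocked biomass reaction, and
growth-dilution corrections would require a different formalism.

The linear stage is degenerate — many flux distributions achieve the same
optimum — so a second, quadratic stage picks the distribution of minimal
squared internal flux subject to the objective staying at its optimum.
All basal quantities (the per-column `v_basal` used by the regulation
interpolation) are read from this stage-2 solution, not the stage-1 vertex:
the stage-1 solution is solver-dependent, whereas the stage-2 minimiser is
unique on the internal columns by strict convexity. Exchange columns enter
the quadratic objective with a negligible weight (1e-8) purely so the
reported vector is fully determined; at that weight the internal solution
is unaffected at the reporting precision.

The objective floor in stage 2 is the inequality `objective >= z*`, not an
equality: when a caller passes a floor below the true optimum the two forms
genuinely differ, and the inequality is the semantics this package
guarantees. Internally the floor is resolved exactly by case analysis (the
minimiser either satisfies it strictly or holds it with equality), which
also avoids solving a QP whose feasible region has lost full dimension.

## Gene regulation semantics

A regulated gene fixes fluxes, not bounds. For strength δ in [0, 1]:

* **up**: the regulated direction is fixed at
  `v_basal + δ (v_max − v_basal)`; δ = 0 reproduces the basal state and
  δ = 1 pins the flux at its flux-variability maximum.
* **down**: symmetric, towards `v_min`.
* **knockout**: both directions fixed to zero.
* **coupled_up**: both directions of a reversible pair are up-regulated
  simultaneously, each against its own range — the mode needed for
  enzymes whose forward and backward reactions must stay in equilibrium
  (fatty-acid oxidation carriers, CoA cycling).

Two design points were genuinely open and are resolved as follows. First,
for up/down regulation of a reversible reaction the regulated *direction*
follows the sign of the basal net flux (forward when non-negative), with
the opposite direction held at basal; this is the only state-dependent
reading under which δ = 0 is exactly the normal state. Second, the
flux-variability ranges feeding the interpolation are computed in "free"
mode — under the normal-state bounds only, without pinning the objective —
because the regulated optimum is re-computed afterwards anyway and an
objective-pinned range would make δ = 1 infeasible for any reaction whose
extreme trades against ATP production. An `objective_fixed` mode is
exposed for sensitivity analysis.

Fixing several columns of one gene simultaneously can be jointly
infeasible even though each value lies in its own range (shared precursor
pools). `max_feasible_delta()` bisects on δ to the `tol = 0.005` level, so
strengths are reportable to the nearest percent; the bisection's
monotonicity premise (feasibility for all δ below a feasible δ) holds
exactly for single-column regulation and is verified empirically against a
0.001-step grid scan for the multi-column constructions in the test suite.
Regulated values are fixed in both solver stages of the deficient state.

## Flux sums, fold changes and similarity

The production rate of a metabolite is the literal one-directional flux
sum: over its non-boundary compartment instances, producers' forward
fluxes plus the backward fluxes of reactions that consume it in the
forward direction. It is a turnover surrogate for a pool size, not a net
balance (which is identically zero at steady state) and not a
concentration. Boundary-compartment instances are excluded because the
quantity stands in for an intracellular pool measured after tissue
homogenisation.

Fold changes use an epsilon policy: rates at or below `eps = 1e-9` (the
solver's noise floor) are vanishing; two vanishing rates give "no change",
one vanishing rate floors that side at `eps` and flags the ratio
"saturated" — the sign is meaningful, the magnitude is not. Change signs
apply a no-change band of `eps_sign = 1e-6` on |log₂ FC|. Similarity
against a reference table defaults to the `"all"` denominator policy: the
denominator is the full reference size and a no-change prediction matching
a no-change reference counts as agreement. The printed similarity ratios
this layout mirrors are integer multiples of 1/36 and 1/21, consistent
with a fixed full-set denominator; a `"defined_only"` policy (both signs
non-zero) is provided because the treatment of no-change entries in the
source screen is not documented. Reference metabolites absent from the
model are dropped from the denominator with a warning — their flux sum is
undefined — or counted as zero-sign misses under `missing = "zero"`.

The packaged transcription of the published arrow table
(`inst/extdata/table1_sign_matrix.tsv`) carries a documented discrepancy:
agreement counts recomputed from the printed per-gene arrows do not
reproduce the printed similarity row exactly under either denominator
policy (the printed ratios imply a 36-entry reference, the table prints 35
rows, and several columns disagree by more than the hidden row could
explain). The fixture keeps both the arrows and the printed row so the
discrepancy stays measurable; nothing in the package silently reconciles
them.

## The synthetic generators

`make_toy_liver_model()` emulates the qualitative topology the screen
needs: glucose uptake and lumped glycolysis, lactate export, oxygen-limited
mitochondrial pyruvate oxidation, glutaminolysis feeding an oxidative ATP
branch, and a decarboxylase side branch (`Ddc`, three parallel
precursor routes) whose amine product must be oxidatively deaminated in
the mitochondrion with α-ketoglutarate as amino acceptor. Capacities
(glucose 10, oxygen 10, glutamine 20, each precursor 1, times
`capacity_scale`) are chosen so cytosolic pyruvate routing and
mitochondrial oxygen are genuinely contested; up-regulating `Ddc` then
necessarily diverts oxygen and demands α-ketoglutarate, reproducing the
aerobic-glycolysis shift (lactate and glutamine up, mitochondrial pyruvate
import down) as a property of the topology rather than a tuned number.
What the toy does **not** emulate: genome-scale redundancy (thousands of
alternative routes), cofactor stoichiometry (ATP yields are lumped),
eight-compartment structure, or realistic uptake kinetics. A passing toy
screen therefore demonstrates the pipeline's correctness, not the
biological fidelity of any particular fold change on a real network.

`make_capped_branch_model()` back-computes a branch cap so the largest
jointly feasible regulation strength is exactly known (default 0.40),
giving the strength search a ground truth. `make_random_balanced_system()`
generates seeded sparse networks at oracle-enumerable scale; every
internal reaction conserves mass (total consumed equals total produced),
so a closed medium provably admits only the zero flux, and a
substrate-to-demand backbone guarantees a positive optimum under the
default medium. `make_sign_table()` constructs references with an exact
number of agreements. All generators restore the caller's RNG state.

## Numerical design

No dependable linear-programming package is available in the target
environment, so the LP stage is a built-in bounded-variable two-phase
primal simplex with Bland's rule (exact vertex arithmetic, explicit basis
inverse — appropriate at desk scale, not for genome-scale models). The QP
stage eliminates equalities (and columns pinned by regulation) through a
QR null-space reduction and hands the reduced box-only problem to
`quadprog`'s dual active-set method. That method can fail spuriously on
degenerate faces — typically when the objective floor equals the true
optimum and many bounds are simultaneously tight — so failures are
arbitrated: a simplex phase-1 run decides feasibility exactly, and
feasible-but-failed problems fall back to an ADMM iteration polished on
its active set and certified against the KKT conditions (stationarity,
feasibility, multiplier signs). Tolerances: feasibility 1e-9, mass-balance
reporting 1e-6, fluxes below 1e-9 treated as zero. Ranking ties break
lexicographically by gene id; reports are byte-deterministic for identical
inputs. Unbounded objectives are reported with an offending column named,
never capped silently.

Problem sizes used by the test and acceptance runs: random systems up to
12 metabolites and 14 reactions (100 seeds for the solver-oracle
comparisons, against an external LP solver and an independent ADMM route),
the 29-reaction toy, and exhaustive sign-vector enumeration up to length
6. These sizes make every oracle exact or effectively exhaustive while the
whole suite stays fast.

## Limitations

* Flux sums are trend surrogates; the method cannot predict metabolite
  concentrations, and saturated fold changes have meaningful sign only.
* Gene handling is a flat gene-reaction list; boolean gene-protein-reaction
  logic (isoenzymes vs complexes) is not evaluated.
* One gene is regulated at a time; combinatorial perturbations are not
  explored.
* The dense simplex and QR reductions are sized for desk-scale models and
  fixtures; genome-scale models load and split correctly, but solving them
  with the built-in solvers is slow and is not the validated regime.
* No thermodynamic (loopless) constraints: detached futile cycles are
  suppressed by the norm objective, but thermodynamically infeasible loops
  that carry objective benefit are not excluded.
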