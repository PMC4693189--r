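---
title: "Diurnal flux balance analysis: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diurnal flux balance analysis: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diufba)
```

## The problem

Phototrophs face a scheduling problem that classical flux balance
analysis cannot express: energy arrives only during the day, but
maintenance costs accrue around the clock. A cell that converts every
photon into functional biomass grows fastest until sunset and then
starves; a cell that stores too much grows slowly. The evolutionarily
sensible objective is *"grow as much as possible while laying down just
enough reserves to survive the night"* — a trade-off across time that a
single steady-state LP cannot see, and that is usually hidden by
hard-coding a measured storage fraction into the biomass function.

`diufba` makes the trade-off part of the optimization while keeping the
problem a single LP.

## The model

Let `S ∈ R^{s×r}` be the stoichiometric matrix, and declare

* two phases, light and dark, with durations `Δt_light`, `Δt_dark`
  (hours) and per-phase bound overrides (e.g. photon uptake shut off at
  night);
* `p` carry-over species — storage metabolites, plus any functional
  biomass pool that must persist overnight;
* `q ≤ p` exportable species whose accumulation may leave the cycle
  (net growth, long-term storage).

The extended matrix replicates `S` block-diagonally and couples the
blocks:

```
        light rxns   transfer   dark rxns   export
S̃  =  [     S           T_L         0         0    ]   (light rows)
       [     0           T_D         S         E    ]   (dark rows)
```

Each transfer column has exactly two nonzeros: `−1` in its species'
light row and `+1` in its dark row; each export column a single `−1` in
the dark row. The variable vector `ṽ` has `2r + p + q` entries.

**Units.** Within each phase conditions are constant (quasi-steady
state), so fluxes integrate trivially: `Δc = v · Δt`. All extended
variables are concentration changes (mmol/gDCW per phase; M per phase in
the example model). Reaction bounds are therefore the phase-specific
flux bounds multiplied by that phase's duration — this is what lets
phases of unequal length share one matrix — and `phase_fluxes()` divides
by `Δt` to recover rates comparable to classical FBA output. Equalities
(`lb = ub`, used for maintenance demands) stay equalities under the
scaling.

**Cyclic closure** is implicit: each phase block must balance, and
transfers are the only inter-phase coupling, so any carried-over amount
that is not exported must be consumed in the other phase. No explicit
periodicity constraint is added.

The LP is `max wᵀṽ s.t. S̃ṽ = 0, ṽ_lb ≤ ṽ ≤ ṽ_ub`. Solutions report
`S̃ṽ` residuals, which must stay below `1e-9` (relative) to count as
optimal.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| phase durations | h | user-set | the photoperiod being simulated |
| transfer bounds | amount | `(-Inf, Inf)` | transfers are reversible reactions; finite bounds are available per species, mainly for phase-plane scans over transfer amounts |
| export bounds | amount | `[0, Inf)` | accumulation leaves the system; it can never enter it |
| objective `w` | — | 1 on each export column | exported functional biomass is the natural growth proxy; with no exports declared, the base model's objective is applied in both phases; fully overridable per column |
| feasibility tolerance | relative | `1e-9` | vertex solutions from a dense simplex on desk-scale models are exact to rounding; the tolerance only guards the residual check |

Two design choices were genuinely open and are worth recording:

* **Export is attached to the dark (final) phase only.** "Accumulation
  beyond the cycle" reads most naturally as end-of-cycle removal.
  Export from the light phase is still expressible by making a species
  exportable and bounding its transfer column.
* **Functional biomass persistence uses the same mechanics as
  storage.** A species that must survive from day to night is declared
  carry-over exactly like a storage metabolite; the
  functional/storage distinction is a reporting label (used by
  `transition_composition()`), not a matrix-level one. The
  transition composition adds light-phase production of
  functional-labelled species (measured as `S · Δc_light`, which under
  cyclic closure equals their transfer amount) to the storage transfer
  amounts, and normalizes.

## The example model and its calibration

The built-in two-phase model (`build_toy_model()`) has four species —
substrate, storage, biomass (in molar precursor units), and a
maintenance sink — and eight reactions. Substrate converts 1:1 to
biomass, storage, or maintenance; storage fuels maintenance and growth
at yield `e_sto`; starving on biomass yields `e_bio` per unit. The
scenario defaults are 1 h of 1 M substrate supply, 0.1 M/h maintenance,
and a 1 h or 2 h dark phase.

The yields are not free knobs. They are pinned by the 1 h:1 h scenario
alone: a myopic day ends with 0.9 M biomass (1 M minus 0.1 M daytime
maintenance) and a starved night burns 0.2 M of it to cover 0.1 M
maintenance, giving `e_bio = 0.1/0.2 = 0.5`; the whole-cycle optimum
stores 0.125 M to cover the same 0.1 M, giving `e_sto = 0.1/0.125 =
0.8`; and `0.1 + 0.775 + 0.125 = 1.0` forces the 1:1 substrate
conversions. The 2 h-night scenario (final biomass 0.65 M vs 0.5 M
sequential; 72.2%/27.8% composition) then serves as held-out validation
of the calibration — none of its numbers were used to fit anything.

The closed form behind the test oracle follows from direct accounting:
storage\* = maintenance·Δt_dark / e_sto, biomass\* = supply −
maintenance·Δt_light − storage\*, valid whenever `e_bio ≤ e_sto` makes
storage the cheapest night fuel (`toy_scenario()` enforces `0 < e_bio ≤
e_sto ≤ 1`; equality makes the optimal *vertex* non-unique but leaves
the optimal *value* unchanged, which is what the lossless-limit test
uses).

```{r oracle}
toy_oracle(toy_scenario())[c("biomass", "storage")]
```

## The sequential comparator

`dfba_soa()` implements the static optimization approach of dynamic FBA
at phase resolution: the light phase greedily maximizes functional
biomass accumulation; end-of-phase pools become bounded supplies for the
dark phase, which maximizes what is left. Pools are realized as
accumulation and source columns on the base network, so the comparator
works for any two-phase model whose carry-over species identify the
pools. Two steps (not a finer grid) suffice because conditions are
constant within a phase. When night maintenance cannot be met from the
pools the run reports `starvation-collapse` rather than an LP error.
Whole-cycle foresight weakly dominates this strategy for every scenario,
strictly whenever the night is non-trivial and storage is lossy — both
facts are asserted in the test suite.

## Phase plane scans and mode classification

`phpp_scan()` fixes one or two extended variables by equality
(`lb = ub = value`) on a grid and re-solves; infeasible cells — including
values outside a variable's hard bounds — are masked, not dropped, so
grids keep their shape. The LP value function is concave and piecewise
linear in these right-hand-side parameters, which yields two checks the
suite enforces: no grid point sits above the chord of its neighbours,
and the unconstrained optimum is attained whenever its coordinates lie
on the grid.

`classify_modes()` labels maximal 4-connected regions of constant
finite-difference gradient (tolerance `1e-6`) as metabolic modes; each
linear piece of the value function corresponds to one active flux
routing. Forward differences (backward at the trailing edge) keep the
kink cell attached to the region whose slope it initiates. Grids with
fewer than three points along every axis are returned as a single region
with a warning. Gradient clustering is our algorithmic interpretation of
drawing mode regions on a phase plane; published mode maps are typically
delineated by inspection, and a shadow-price-based classification would
be a reasonable alternative we did not pursue.

## Numerical choices

The LP engine is a dense two-phase bounded-variable primal simplex with
Bland's anti-cycling rule, written for this package (the hosting R
environment offers no dependable LP package; an external cross-check
against `scipy.optimize.linprog`/HiGHS on randomized instances is part
of the test suite, kept strictly on the oracle side). Free variables
(unbounded transfers) are handled natively — no big-M surrogate bounds.
The basis system is re-factorized at every pivot: transparent and exact
to rounding at desk scale, at the cost of speed on genome-scale models,
where a sparse revised simplex or an interior-point method would be the
upgrade path. Fixed variables (`lb = ub`) never enter the basis;
degenerate pivots are accepted (Bland guarantees termination).
Infeasibility is declared when phase-1 artificial variables cannot be
driven below `1e3 ×` the scaled tolerance.

The secondary `min_total_flux` stage re-solves at the fixed optimal
objective with split variables (`v = v⁺ − v⁻`), a standard
alternate-optima control. The toy scenarios are engineered so the
optimal vertex is unique (no futile sinks; export only for biomass), so
tests of printed values do not depend on it.

Serialization writes 15 significant digits so coefficients like 0.8 or
1/3 survive TSV/JSON/SBML round trips bit-equal; infinite bounds map to
`INF`/`-INF` in SBML parameters and `"inf"`/`"-inf"` in JSON, the
conventions of the field's toolchains.

## What the tests do and do not show

Everything quantitative in the suite runs at desk scale: the 8-reaction
example model (19 extended columns), randomized chain networks of 3–6
species for the decoupling and solver batteries, a ~60-point scenario
sweep for the oracle-equivalence and dominance properties, and a
9-reaction two-compartment synthetic phototroph exercising the SBML
pipeline end to end. These sizes keep the full suite near ten seconds
and are entirely adequate for *structural* claims — block assembly,
conservation, concavity, dominance, exactness of the LP against closed
forms.

They deliberately do not demonstrate genome-scale behaviour: no
gene–protein–reaction rules, no compartment semantics beyond id tags, no
degenerate alternate-optima landscapes of real reconstructions, and no
literature growth-rate comparisons, which require a curated organism
model and its (unpublished) objective and maintenance settings. The
machinery accepts any SBML-FBC model through the same entry points, so
such a study is a configuration exercise, not a code change. N-phase
(>2) configurations are constructible but outside the validated path,
and dynamic-FBA-style kinetic uptake laws are out of scope by design —
the point of the formulation is to keep the diel problem convex.
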