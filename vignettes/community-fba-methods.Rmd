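---
title: "Host–symbiont community flux balance analysis: model and methods"
author: "symbioFBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Host–symbiont community flux balance analysis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbioFBA)
```

# The biological problem

The pea aphid hosts an obligate intracellular symbiont, *Buchnera
aphidicola*, that synthesizes the essential amino acids its phloem diet
lacks, and frequently a facultative hemolymph symbiont, *Hamiltonella
defensa*. *Buchnera*'s histidine pathway produces AICAR as a 1:1
stoichiometric by-product, and because *Buchnera* has lost the proximal
de novo purine pathway, AICAR is also its only purine precursor.
Histidine production is therefore pinned from two sides: the community's
histidine demand and *Buchnera*'s own AICAR demand. Whenever total
histidine demand (host + histidine-auxotrophic *Hamiltonella*) exceeds
the purine-driven AICAR consumption, the surplus AICAR must overflow out
of *Buchnera*. This package quantifies that coupling with
multi-compartment flux balance analysis (FBA) and provides the
surrounding numeric procedures such studies need (ratio conversions,
¹³C enrichment summaries, performance metrics, metabolite screening).

# The community model

## Compartments and the shared pool

Each organism is a stoichiometric model (`OrganismModel`): metabolites
with compartments, reactions with bounds in mmol·gDW⁻¹·h⁻¹, and a kind
label (internal, transport, exchange, demand, biomass). At assembly
(`assembleCommunity`), metabolite, reaction and compartment ids are
suffix-tagged with the organism (`his__Buchnera`); a collision after
tagging is an error, never a silent rename. Metabolites flagged
`transportable` (or an explicit allow-list) are *linked*: each gets a
shared-pool ("hemolymph") counterpart, one reversible transport reaction
per organism (`T_his__Buchnera`; positive flux = export to the pool,
stoichiometry −1/+1 of the same chemical species), and one pool exchange
reaction (`EX_his__pool`; positive flux = export out of the community).
The growth medium constrains only pool exchanges: a listed metabolite
with maximum uptake ρ gets lower bound −ρ (uptake is negative flux);
unlisted exchanges get lower bound 0, leaving secretion open.

## Biomass-ratio coupling

All community fluxes are expressed per gram dry weight of a *reference*
organism (*Buchnera*). An organism present at biomass *r* grams per gram
of reference contributes *r* × (its per-gram flux) to the community, so
its bounds and fixed demands are multiplied by *r*. The published
constraint tables for the original three-compartment aphid model are not
distributed with the paper's text, so this scaling convention is the
package's own, stated here prominently: it keeps the community a single
LP and makes the biomass sweep a pure rescaling (`setBiomassRatio` is
exact and idempotent). The scaling-consistency property — per-gram
symbiont fluxes are invariant when *r* changes — is tested.

## The host as fixed demands

The host is represented by pinned demand fluxes on the pool (histidine
drain h_A) plus free accumulation sinks, not by a growth objective. This
matches the assumption of a fixed aphid demand for histidine that the
sweep experiment relies on. Two sinks matter:

* a free AICAR sink — the destination of the overflow;
* a free histidine sink — used only when *Buchnera*'s purine demand
  forces histidine production above total demand. Without it the model
  would be infeasible for parameter sets with a > h_A + b + r·h_H,
  because the co-produced histidine would have nowhere to go at steady
  state. This is a deliberate modeling choice, the mirror image of the
  AICAR sink.

An objective-driven host (maximize a flux, e.g. histidine delivery) is
available through `solveFBA`'s explicit objective argument.

# Solving

FBA is the LP max c᷆ᵀv s.t. S·v = 0, lb ≤ v ≤ ub, with fixed demands
pinned lb = ub. The paper-style readouts use **parsimonious FBA**: among
all feasible (or objective-optimal) flux distributions, minimize total
absolute flux Σ|v| via flux splitting v = p − q, p, q ≥ 0, with the box
bounds mapped exactly onto p ∈ [max(lb,0), max(ub,0)],
q ∈ [max(−ub,0), max(−lb,0)]. Flux selection rules are rarely printed in
applied FBA studies; pFBA is this package's explicit, documented choice
because it yields a unique, economical distribution and provably
excludes futile cycles (tested: the two-compartment toy's minimal total
flux is exactly the hand-counted 7 units). Flux variability analysis
brackets each reaction's flux subject to Σ|v| ≤ (1+γ) times the pFBA
optimum; γ = 0 certifies uniqueness.

## Numerical choices

* LP back end: a bounded-variable two-phase revised simplex with Bland's
  anti-cycling rule (R/lp.R). Flux-splitting LPs are heavily degenerate;
  Bland's rule guarantees finite termination and determinism —
  identical inputs give bit-identical solutions. Pivot tolerance 1e-9,
  phase-1 feasibility threshold 1e-7, mass-balance reporting tolerance
  1e-6 (`checkBalance`).
* Bounds are finite by convention: unconstrained reactions use ±1000
  mmol·gDW⁻¹·h⁻¹ (the constraint-modeling default, also applied to SBML
  files that omit bounds, with lb = 0 for irreversible reactions). This
  makes every LP bounded, so an "unbounded" status cannot arise in
  practice and infeasibility is always reported as a status, never as
  silent zeros.
* Orderings are deterministic: the stoichiometric matrix sorts
  metabolite and reaction ids.
* Correctness is cross-checked against an independent oracle: on small
  networks, exhaustive enumeration of active-set points (every
  assignment of reactions to {lower bound, upper bound, zero, free})
  reproduces the pFBA optimum to 1e-6.

# The toy symbiosis and its closed form

`makeToySymbiosis` collapses the coupling into four rates (all per gDW
*Buchnera* per h): host histidine demand h_A = 1.0, *Buchnera* AICAR
consumption for purines a = 1.0, *Hamiltonella* per-gram histidine
demand h_H = 0.0536, *Buchnera* self-use b = 0, with a PRPP uptake cap
of 10. The pFBA solution is closed-form:

v_his(r) = max(a, h_A + b + r·h_H),  overflow(r) = max(0, h_A + b + r·h_H − a).

The defaults are a calibration, not a measurement: a = h_A makes the
symbiont-free baseline overflow exactly zero, and h_H is set so the
empirically observed 6.7:1 Buchnera:Hamiltonella biomass ratio
(r = 1/6.7) raises HisD flux by 0.8 % — the two anchors at which the toy
mirrors the genome-scale model's published behavior. Away from those
anchors the toy is linear in r and intentionally differs from the
genome-scale model (toy: +26.8 % at 1:5; genome-scale: considerably
steeper), because a lumped three-reaction network cannot reproduce a
full metabolic network's flexibility. The default sweep grid
{10:1, 5:1, 6.7:1, 2:1, 1:1, 1:2, 1:5} covers the published range
endpoints plus the empirical ratio. The true per-gram histidine demand
of *Hamiltonella* is unknown; h_H is a free parameter.

Because baseline overflow is exactly 0, fold changes against it are
undefined; `runRatioSweep` substitutes a floor of 1e-9 numerically and
the TSV writer prints non-finite folds as `Inf`.

```{r toy}
toy <- makeToySymbiosis()
sweepTable(runRatioSweep(toy$spec, c("10:1", "6.7:1", "1:1", "1:5")))
```

# Ratio conversions

Biomass and cell-number ratios are linked by a per-cell mass factor
calibrated from one matched pair: factor = (cells_H/cells_B) /
(mass_H/mass_B). The published pair 1:5 biomass ↔ 1:130 cells gives
factor 26 (one *Buchnera* cell weighs 26× one *Hamiltonella* cell);
applied to the measured 1:3.9 cell ratio it returns a 6.7:1 biomass
ratio (2 significant figures, the reporting convention of
`formatRatio`). Ratio strings are `a:b` with decimals allowed; the
internal scalar is r = b/a grams of symbiont per gram of reference.

# ¹³C isotopologue enrichment

For a compound fed as a uniformly ¹³C-labeled tracer, the isotopologue
peak areas A₀..A_k yield fractions A_k/ΣA and a ¹³C/¹²C label ratio.
Two ratio modes are first-class, because published figures often do not
state which was used: `all-labeled` (Σ_{k≥1}A_k / A₀, the default —
partially labeled isotopologues are routinely abundant) and `m6-only`
(A₆/A₀ for the fully labeled species). The identity
ratio_all = (1 − f₀)/f₀ and invariance to area rescaling are tested. No
natural-abundance correction is applied by default. Group summaries are
tested pairwise with a pooled t; when both soluble and protein fractions
are tested, the critical probability is Bonferroni-adjusted to
α/2 = 0.025.

# Performance metrics and the metabolite screen

`pooledTSummary` computes t = (m₁−m₂)/√(se₁²+se₂²) with
df = n₁+n₂−2 directly from printed summaries; for equal group sizes this
is *exactly* the textbook pooled t on the raw samples (tested by brute
force against `t.test`). Published degrees of freedom in this system
match the pooled convention, which is why pooled rather than Welch is
the default. RGR = ln(w₇/w₂)/5 and r_m = 0.745·ln(M_d)/d are direct
formula implementations.

The metabolite screen mirrors the two-stage practice in metabolomics:
stage 1 runs an uncorrected per-feature two-sample t test to flag
candidates; stage 2 refits each candidate with a linear mixed model
(symbiont status fixed, aphid genotype random intercept, REML via
`lmerTest`, Satterthwaite p values) and applies Benjamini–Hochberg over
the stage-2 p values. Mixed-model fitting is deliberately delegated to
lme4/lmerTest — re-implementing REML would be out of proportion — while
the screening order, candidate selection and BH step are the package's
own. With fewer than two genotypes per status level the mixed stage is
impossible and the screen falls back to t-only with a warning.

Two statistical facts about this design are worth stating because the
synthetic-data tests depend on them. First, when symbiont status is a
property of the genotype (naturally infected vs uninfected lines),
genotype variance inflates the naive stage-1 t test far beyond its
nominal α — on genotype-structured null simulations about 40 % of
features get flagged at α = 0.05. That inflation is the very phenomenon
that makes the mixed-model stage necessary; stage-1 α calibration is
therefore only asserted on i.i.d. null data, where it is a true binomial
property. Second, "no significant features after BH" on a *single* null
dataset is a high-probability event, not a certainty: selection by
stage 1 enriches small stage-2 p values, and with few genotypes the
Satterthwaite test has low denominator df. The tests assert the
published nothing-significant pattern as the median outcome over fixed
replicate simulations, plus an order-of-magnitude reduction from
stage-1 flags to BH hits in every replicate.

# Synthetic data: what it does and does not emulate

All generators are pure functions of their parameters and an explicit
seed (`withr::with_seed`; the ambient RNG stream is untouched).

* Isotopologue tables: areas = total × fraction × lognormal(mean 1,
  cv) — multiplicative noise, since peak areas are positive and
  right-skewed. No detector saturation, no retention-time artifacts, no
  natural-abundance envelope.
* Metabolomics matrices: log-abundance = feature baseline +
  per-feature genotype intercept (sd = genotypeSd) + status effect +
  Gaussian noise, with half the genotypes symbiont-positive. Real
  metabolomes add correlated features, batch effects and
  missingness — passing tests show the screening logic is correct, not
  that it is robust to those.
* Random networks: a guaranteed-feasible exchange→chain→demand backbone
  plus random shortcuts; property-test fuel, not realistic genome-scale
  topology.
* Performance samples: plain normal draws behind printed mean ± SE.

# Scope of the validation runs

The packaged checks run the toy and property suites at sizes chosen to
exercise every code path thoroughly while staying quick on a laptop:
20 random toy parameter sets × 50 ratio points for the analytic-curve
equivalence, networks of up to 8 reactions for the exhaustive LP oracle
(the active-set enumeration grows as 4ⁿ), 500-feature i.i.d. and
120-feature genotype-structured screening matrices, and 200 synthetic
isotopologue tables. The genome-scale deposited community model is not
bundled (it is distributed through BioModels/GitHub); the SBML importer
and sweep accept it, the import preserves its ids verbatim, and the
reaction-role mapping (which ids are HisD and the AICAR transport) is
configuration, since its internal naming scheme is not described in
print.

# Known limitations

* Static FBA only: no dynamic community simulation, no growth-rate
  coupling between organisms, no thermodynamic constraints, no MILP
  (knockouts), no flux sampling.
* SBML import is read-only, Level 3 core + fbc bounds; annotations,
  groups and gene-product associations are ignored; SBML export is not
  provided.
* The host-as-fixed-demand formulation cannot capture host metabolic
  rerouting in response to symbiont load; the observed empirical
  histidine response exceeding the model prediction is exactly the kind
  of host-side effect this formulation excludes by construction.
* Mann-Whitney and the normality/homoscedasticity advisory checks are
  delegated to base R; test choice is explicit configuration, never
  silent auto-switching.
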