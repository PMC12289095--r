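---
title: "Classifying pairwise bacterial interactions across environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying pairwise bacterial interactions across environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairfba)
```

## The model

A metabolic model here is a stoichiometric matrix $S$ (rows: compounds,
columns: reactions), flux bounds $l_v \le v \le u_v$, and a biomass
reaction whose flux is read as the growth rate $\lambda$
(mmol gDW$^{-1}$ h$^{-1}$ throughout). Compounds live in an extracellular
compartment shared with the world (and, in a pair, with the partner) or
in intracellular compartments (cytoplasm; periplasm is treated as
intracellular everywhere). There are no source or sink columns: nutrient
availability enters as bounds on the net-change (right-hand-side) vector
$c = S v$. Intracellular rows are pinned at $c = 0$ (no internal
accumulation); extracellular rows satisfy $l_c \le c \le u_c$, where a
negative $l_c$ is a supply (net uptake allowed) and a positive $u_c$ an
export allowance. We call the set of compounds with $l_c < 0$ the
*environment*. Standard SBML models express the same thing with exchange
reaction columns; `canonicalize_model()` folds those columns into
default-environment bounds so both conventions meet in one internal form.

The growth of one organism in an environment is the linear program

$$\max \; \lambda \quad \text{s.t.} \quad S v = c,\;
l_v \le v \le u_v,\; l_c \le c \le u_c,$$

with intracellular $c$ fixed at zero (`solve_individual_growth()`).

## Pairs and the no-harm constraint

For a pair, the combined matrix shares the extracellular rows (net change
is the sum of both organisms' contributions) and keeps each organism's
intracellular block separate (`build_pair_model()`). The interaction is
read from four numbers: each organism's maximal growth alone,
$\lambda_i$, $\lambda_j$, and each organism's maximal growth together,
$\lambda_i^*$, $\lambda_j^*$, where the together-value maximizes the
focal organism's biomass subject to the *no-harm* constraint that the
partner can still reach its alone-growth, $\lambda_j^\dagger \ge
\lambda_j - \epsilon$ (`solve_pair_growth()`). The two directed solves
are independent; there is no joint objective. Because the partner's solo
optimum plus zero focal flux is always feasible, the floored program can
never be infeasible when the solo programs are — the implementation
treats such an infeasibility as an internal error, not a result. A floor
of zero (partner cannot grow alone) is clamped at zero rather than
$-\epsilon$, so it constrains nothing.

Per organism, the comparison of $\lambda^*$ against $\lambda$ yields a
symbol: worse (`-`), equal (`=`), better (`+`), with `+`/`=` upgraded to
`x` when the organism is non-viable alone but viable together. The label
is then:

| symbols | label |
|---|---|
| any `-` | COMPETITIVE |
| `=`/`=` | NEUTRAL |
| `+`/`=` | COMMENSAL |
| `+`/`+` | FACULTATIVE_COOP |
| `x`/`+` | ONEWAY_OBLIGATE |
| `x`/`x` | TWOWAY_OBLIGATE |
| `x`/`=` | OBLIGATE_COMMENSAL |

The exploitative combinations (`+`/`-`, `-`/`+`) cannot occur: a focal
improvement is only accepted while the partner keeps its alone-growth,
so any solution improving one organism certifies the other is not
harmed. This is asserted at run time and property-tested over random
pairs. An organism left below the viability threshold together (and no
loser) gives NO_GROWTH. The order of these rules matters and was chosen
so that a genuine loser always reads as competition, even when the
no-harm floor leaves the focal organism only a sliver of flux — the
shared-substrate fixture `COMP` is exactly that case
($\lambda^* = \epsilon$ for both).

## Tolerances

Two tolerances drive everything (`tolerance_config()`):

* `eps_class = 0.001` — growth-rate comparison tolerance; also the slack
  on the no-harm floor. Dimensionless in the units of $\lambda$.
* `eps_grow = 0.1` — viability threshold: below it an organism "cannot
  grow", both for obligacy subtyping and for calling an environment
  viable. The essential-compound screen uses it as its joint-growth
  criterion; we also use it for screening viability, since no separate
  screening threshold is stated anywhere and the two uses are the same
  judgment. Both are configurable; the LP solver tolerance (1e-10) sits
  far below `eps_class`.

## Environments: usable, essential, random

For a pair, *usable* compounds are the extracellular compounds touched by
at least one reaction of the combined matrix. The *essential* set is
found by supplying every usable compound at once (the replete
environment, supply $-1000$ like generated environments — no separate
replete value is stated, so one standard is used) and removing each
compound singly: if the pair can no longer grow together (either
directed $\lambda^*$ falls to `eps_grow` or below), the compound has no
substitute and is essential. Essentiality tests joint growth only; a
compound both organisms can live without individually can still be
essential to the pair, and vice versa. The screen errors when the pair
cannot grow together even in the replete environment — which is the
honest answer for pure shared-substrate competitors, whose directed
$\lambda^*$ never exceeds `eps_class` in any environment.

Random environments (`generate_random_environment()`) contain all
essential compounds plus a fixed number of substitutable compounds drawn
uniformly without replacement, every present compound supplied at
$l_c = -1000$ (configurable, e.g. $-500$ for supply-sensitivity runs).
Upper bounds always stay at the pair's combined defaults — the
per-compound sum of the two models' default environments — so export
capacity is never randomized, and compounds absent from both defaults
cannot be net-secreted.

## Screening, single removals, degradation

`screen_pair()` samples environments until a target number are *viable*
(both directed $\lambda^* \ge$ `eps_grow`), classifying each.
Proportions over viable environments split into competitive /
cooperative (facultative + one-way + two-way obligate) / other (neutral,
commensal, obligate-commensal), and cooperative environments are
subtyped by alone-viability. Sampling is with replacement across
attempts; one seed fixes the whole stream, and the attempt cap defaults
to ten times the target (unstated in the study design; partial screens
are flagged, not errors).

`single_removal_scan()` removes each non-essential present compound
independently from the full starting environment and re-classifies;
outcomes are bucketed by destination label, with all three obligate
labels pooled into `to_obligate`.

`degrade_environment()` first strips the environment to the compounds
actually *used*. Optimal flux vectors are not unique, so "used" is made
deterministic by a secondary objective: holding both directed optima
fixed (within `eps_class`), total absolute environmental uptake is
minimized, and a compound counts as used when either directed solution
still imports it (above 1e-6). This may retain fewer compounds than an
arbitrary solver solution would; the reduction must not change the label
(an internal consistency check). From the reduced environment, random
orderings of the non-essential compounds are removed one at a time until
at least one organism's directed $\lambda^*$ drops below `eps_grow`; a
state that fails that viability test is recorded as NO_GROWTH whatever
its symbols would say, because the walk's stopping rule is "someone can
no longer grow". Since removals only shrink the feasible region, solo
growth is non-increasing along every path and obligacy can never be
lost — both are asserted in the property suite. Path summaries report
removals before the first label change (paths that never change are
censored at their full length and flagged), collapsed transition
sequences, and the share of collapsed paths whose last state before
NO_GROWTH was obligate.

## Cross-environment statistics

* `jaccard_distance()` on environment compound sets (two empty sets have
  distance 0).
* `compound_bias()`: per-compound competitive-appearance share against
  the global share, with an exact two-sided binomial null by default
  (labels reassigned independently with the global probability); a
  Monte-Carlo label-resampling variant is available. Raw p-values are
  primary, with a Benjamini–Hochberg column alongside.
* `switch_frequency()`: per-compound observed switch counts against the
  null that every removable compound in an environment was equally
  likely to have caused that environment's switches; expected counts sum
  exactly to the observed total, and significance is upper-tail
  Monte-Carlo over within-environment reassignment.
* `complexity_terciles()`: models scored by usable-metabolite or
  reaction counts and cut at the 33.3rd/66.7th percentiles; boundary
  ties fall to the lower category so identical metrics always share a
  category.

## The synthetic generator

The toy models replace genome-scale collections in all tests. Named
fixtures (`make_fixture()`) implement one topology per label — shared
single substrate (COMP), reciprocal byproduct cross-feeding (FAC), one-
and two-way obligate coupling through secreted intermediates (OBL1,
OBL2), and disjoint substrates (DISJOINT) — with supply $-10$ and unit
yields so every optimum is a small hand-checkable integer (COMP:
$\lambda^* = 0.001$ each; FAC: 10 alone, 20 together; OBL2: 0 alone, 10
together). `random_toy_pair()` builds linear transport–catabolism–biomass
chains over private, shared, and cross-fed resources with seeded
randomness; its reaction capacities are set far above any feasible
nutrient throughput (1e6) so that in screens at supply $-1000$ the
environment, never an arbitrary enzyme cap, is the binding constraint.
Random pairs carry no ground-truth label on purpose: they exercise
invariants (no exploitation, supply monotonicity, conservation under
shared-resource competition, obligacy monotonicity), not label
expectations.

What the toys emulate: compartment structure, right-hand-side
environments, cross-feeding and competition topologies, default
environments guaranteeing solo growth. What they do not: network size
(tens of reactions, not thousands), cofactor coupling, alternative
pathways with different yields, realistic default-media composition.
Passing tests therefore certify the machinery — the linear programs, the
taxonomy, the screening and perturbation logic — not any biological
claim about particular organisms. Against real collections the analysis
scripts are expected to show the study's qualitative directions (e.g.
more obligate cooperation in less diverse environments, one-way obligate
as the modal cooperation subtype); on the toy scale the analysis scripts
use environment sizes of 30% and 60% of each pair's substitutable pool,
the proportional analogue of 50- vs 100-compound environments over a
~177-compound usable set.

## Numerical choices

* LPs are solved with `boot::simplex` (two-phase primal simplex) behind a
  bounded-range interface. Equalities and zero-rhs $\ge$ rows are emitted
  as pairs of $\le$ rows so phase 1 starts from feasible slacks; only
  strictly-positive-rhs rows (the partner floor) use artificial
  variables. Infinite bounds are capped at $10^7$, and an optimum pressing
  such a cap is reported as unbounded rather than trusted.
* The test suite cross-checks growth rates against an independently
  assembled formulation solved by scipy's HiGHS (a different backend
  entirely), to $10^{-6}$, over random pairs and environments.
* Degenerate optima: only objective values are contracts. Flux vectors
  are exposed but not unique; the only consumer that needs a
  deterministic flux pattern (used-compound reduction) imposes the L1
  secondary objective described above.
* Problem sizes in the default test-and-analysis runs: ~10–60 reactions
  per pair, 1000 random property draws, 100-case oracle batches, 300
  degradation paths — chosen to keep a full run in the low minutes while
  still exercising every code path.

## Limitations

Interactions are *potentials*: flux balance analysis says what growth
rates are achievable, not which regulation realizes them, and exploitation
is deliberately outside the optimization scheme. Only pairs are modeled
(no higher-order effects), metabolisms are static, and obligacy is judged
in the same environment as the pair solve, not in default media. The
essential-compound screen is necessary-not-sufficient by construction:
essential sets do not generally support growth on their own.
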