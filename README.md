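# pairfba

Are two bacteria competitors or cooperators? Usually the honest answer is
"it depends on the medium". **pairfba** classifies the potential
interaction of a pair of bacteria in a given chemical environment from
their genome-scale metabolic models, and then maps how that interaction
shifts as the environment is varied, perturbed, or degraded. It is aimed
at microbial ecologists and systems biologists who work with
constraint-based models (AGORA- or CarveMe-style SBML reconstructions)
and want pairwise interaction calls that are explicit about their
environmental context.

## The method

Growth is computed by flux balance analysis. For one organism in an
environment,

```
maximize   lambda  (biomass flux)
subject to S v = c,   l_v <= v <= u_v,   l_c <= c <= u_c,
```

where nutrient availability is encoded as bounds on the net-change
(right-hand-side) vector `c` of extracellular compounds — compounds with
`l_c < 0` are the *environment* — and intracellular net change is zero.
For a pair, the stoichiometric matrices are combined over a shared
extracellular compartment and each organism's maximal growth `lambda*`
is computed under a **no-harm constraint**: the partner must still be
able to reach its alone-growth `lambda` (within a tolerance
`eps = 0.001`). Comparing alone vs together growth per organism gives
the interaction label:

* any loser → **competitive**
* both better off → **cooperative**, subtyped *facultative*,
  *one-way obligate* or *two-way obligate* by which partners are viable
  alone (`eps_grow = 0.1`)
* otherwise neutral / commensal / obligate-commensal.

Exploitative outcomes (`+/-`) are impossible under this scheme, by
construction. On top of the classifier sit: identification of *usable*
and *essential* compounds for a pair, random fixed-size environment
generation (essential compounds plus uniformly sampled substitutable
ones at supply −1000 mmol gDW⁻¹ h⁻¹), environment screening with
cooperation subtyping, single-compound-removal stability scans,
sequential environment degradation with path summaries, and
cross-environment statistics (Jaccard distances, compound-appearance
bias, switch frequencies, complexity terciles). A synthetic toy-model
generator provides fixtures with analytically known interactions, so the
entire pipeline is testable without external model downloads.

## Worked example

The `FAC` fixture is a pair of reciprocal cross-feeders: A eats X and
secretes Y, B eats V and secretes Z, and each can also burn the other's
byproduct.

```r
library(pairfba)

fx   <- make_fixture("FAC")
assess_pair(fx$models[[1]], fx$models[[2]], fx$env)
#> <interaction_assessment> FACULTATIVE_COOP (+/+)  lambda alone = (10, 10), together = (20, 20)
```

Each organism grows at 10 alone (its private 10 units of substrate) and
at 20 together (its substrate plus the partner's byproduct): facultative
cooperation. Essentials and degradation:

```r
pair <- build_pair_model(fx$models[[1]], fx$models[[2]])
sets <- find_essential_compounds(pair)
sets
#> <pair_compound_sets> 4 usable, 0 essential, 4 substitutable

env4 <- growth_env(lower = c(X = -10, V = -10, Y = -10, Z = -10),
                   upper = pair$default_env$upper)
path <- degrade_ordering(pair, env4, c("Y", "Z", "V", "X"))
path$labels
#> [1] "FACULTATIVE_COOP"   "FACULTATIVE_COOP"   "FACULTATIVE_COOP"
#> [4] "OBLIGATE_COMMENSAL" "NO_GROWTH"
```

No compound is essential (every one has a substitute), but as the
environment degrades the interaction slides from facultative cooperation
into an obligate state — B survives only on A's byproduct once V is
gone — and finally to growth collapse: the characteristic drift toward
obligacy in poorer environments.

## Analysis workflow

The `analysis/` scripts run the full study pipeline over the synthetic
population and write tables under `results/`:

1. `01_fixture_atlas.R` — designed-interaction atlas with growth rates.
2. `02_environment_screen.R` — random-environment screens at two
   environment sizes; interaction and subtype shares per pair.
3. `03_single_removal.R` — single-compound-removal scans and
   per-compound switch frequencies against the equal-likelihood null.
4. `04_degradation.R` — sequential degradation paths, first-change
   distributions, terminal-state shares.
5. `05_environment_stats.R` — Jaccard distances, compound bias,
   complexity terciles.

Run each with `Rscript analysis/0X_*.R`. With SBML collections on disk,
`read_sbml_model()` + `canonicalize_model()` feed real reconstructions
into the same functions.

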