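---
title: "Methods: soil food-web energetics from sample records to treatment contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: soil food-web energetics from sample records to treatment contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilflux)
library(dplyr)
```

`soilflux` turns raw faunal sample records from a nested mesocosm experiment
into per-community trophic networks, steady-state energy fluxes decomposed
by trophic function, community metrics, and treatment contrasts. This
vignette is the package's own account of the science: the models, their
assumptions, the parameters that matter, and the choices made where more
than one defensible option existed.

## 1. From samples to communities

Each mesocosm (a 50 cm diameter lysimeter) is sampled with three devices:
one 15 cm core for macrofauna, one 5 cm core for mesofauna, and three pooled
2 cm cores for nematodes, all to 10 cm depth. Counts scale to the mesocosm
by surface-area ratio; the sampled 10 cm layer is taken as representative of
the fauna accessible to the samplers, so all densities are *per mesocosm*,
not per unit area — every mesocosm shares one geometry, so the distinction
never affects contrasts.

Nematodes are extracted from a known fresh-soil mass, so their counts pass
through two extra conversions: individuals per gram of *dry* soil (divide by
fresh mass × dry fraction) and then per mesocosm via dry bulk density
(g/cm³) times the reference soil volume (mesocosm surface × 10 cm). Only a
subsample (≤ 100 individuals) is identified to taxon; the total density is
apportioned proportionally to the identified composition, which conserves
the total exactly.

Body masses come from group-specific allometric regressions applied *per
measured individual* (up to 10 per taxon per mesocosm), then averaged.
Applying the regression to the mean length instead would bias masses low for
convex power laws (Jensen's inequality); the per-individual route preserves
the population mean. Log-scale regressions are back-transformed before
averaging for the same reason. A taxon without measurements in one mesocosm
falls back to its cross-mesocosm mean estimated mass, and failing that to a
reference mass in the trait table (`fixed_body_mass`, the normal route for
nematode genera, whose masses come from reference compilations rather than
measurement).

Three community metrics summarise each mesocosm:

* **biomass** — Σ density × mean mass (mg per mesocosm);
* **CWM body mass** — exp of the abundance-weighted mean of ln(mass).
  Whether a CWM of body mass should weight by abundance or biomass, and
  average arithmetically or on the log scale, is genuinely open; we weight
  by abundance and average logs because body-mass distributions are heavily
  right-skewed, responses are analysed on the log scale, and an
  abundance-weighted log mean responds to compositional shifts (more small
  individuals) exactly the way the "community-average body size" notion
  intends. Biomass weighting would let a single earthworm dominate the
  metric.
* **diversity** — exp of Shannon entropy of relative biomass: an effective
  number of taxa, 1 for a monoculture, equal to richness for perfectly even
  biomass.

## 2. The diet matrix

Consumer diets start from per-taxon *general preferences*: fractions of the
diet drawn from animal, plant, microbial and detrital resources, summing to
at most 1. These are user-supplied configuration (shipped with documented
example tables) because they come from published syntheses whose numeric
values are external to this package.

The animal fraction is then refined per mesocosm, multiplicatively:

```
weight(prey i) = P_link(mass ratio) × agility_mod × defense_mod
                 × stratum_overlap × biomass_i
```

* **Link probability**: logistic(b0 + b1·r + b2·r²) with
  r = log10(M_pred/M_prey) and b2 ≤ 0, a hump-shaped feasibility curve with
  optimum at −b1/(2b2). The default coefficients (−1, 1.5, −0.5; optimum
  near a predator:prey ratio of 10^1.5 ≈ 32) are *illustrative*: real
  analyses should supply coefficients estimated from interaction databases.
* **Agility**: agile prey are discounted by
  `(1 − agility)·k + (1 − k)` with strength `k` (default 0.5); `k = 0`
  disables the modifier, `k = 1` makes the weight proportional to
  1 − agility.
* **Defense**: defended prey (sclerotized or chemically protected) are
  multiplied by a single factor (default 0.5).
* **Stratification**: a 3 × 3 overlap matrix over
  epigeic/hemiedaphic/euedaphic, default 1 on the diagonal, 0.5 between
  adjacent strata, 0 between surface and deep soil.

The published refinement scheme this emulates does not print its weighting
functions, so the modifier forms above are declared package defaults, kept
deliberately simple (bounded, monotone, each switchable off) and exposed in
`diet_config()`. The order of multiplication is immaterial; self-predation
is excluded (taxon-level resolution cannot represent cannibalism
meaningfully).

Each basal fraction (plant/microbe/detritus) is spread over the matching
resource nodes — uniformly by default, or proportionally to configured pool
biomasses; the "relative biomass" refinement concerns animal prey, so basal
pools stay unweighted unless the user opts in. If a diet component is
locally absent (no prey with positive weight, no node of that type), its
fraction is redistributed proportionally over the remaining components;
this keeps every consumer column exactly stochastic without inventing
resources, and a consumer with *no* available component is a hard error. The
result is a column-stochastic matrix W over animal-then-basal nodes, the
single structural input to the flux solver.

## 3. Steady-state fluxes

Metabolic loss of an average individual is
`exp(ln x0 + a·ln M − E/(kT))` (J/h; M in mg, T in Kelvin, k = 8.617e-5
eV/K), times density for the population. The generator's default
coefficients (ln x0 = 23.055, a = 0.695, E = 0.686 eV) are the published
invertebrate-level regression values; group-specific values are per-taxon
columns in the trait table. Temperature defaults to 288.15 K (15 °C, a
controlled-climate setting) and is shared by all mesocosms.

Under the steady-state assumption, each animal node's energy gain balances
its losses:

```
ē_j G_j = X_j + Σ_k W[j,k] G_k,    ē_j = Σ_i e(type of i) W[i,j]
```

Assimilation efficiencies attach to the *resource* type (0.906 predation
and microbivory, 0.545 herbivory, 0.158 detritivory — configurable), so a
consumer's effective efficiency ē_j is its diet-weighted mixture. Basal
nodes have no balance equation. The linear system is solved densely
(`solve()`); webs have tens of nodes, so a direct solve is exact and fast,
and the test suite checks it against an independent damped fixed-point
iteration (`G ← (X + W_aa G)/ē`) to < 1e-8 on a thousand random webs.

Numerical conventions:

* **Residuals** are reported per consumer as
  `|ē G − X − outflow| / max(X, ē G, ε)` and must be < 1e-8.
* **Negative solutions** (possible with strongly cyclic predation and low
  efficiencies) are a hard `infeasible steady state` error naming the nodes
  — never clipped, because they indicate a preference/metabolism
  combination the user must see. A singular system errors as `degenerate
  food web`. Tiny negative round-off (|G| < 1e-10 relative) is truncated to
  zero.
* **Decomposition** — predation/herbivory/microbivory/detritivory are row
  sums of F = W·diag(G) by resource node type, and the reported total is
  defined as their sum, so additivity is exact by construction.
* All-zero losses produce the trivial all-zero steady state, not an error.

Randomly generated test webs cap each consumer's animal diet fraction at
0.6: with the default efficiencies this guarantees
a_j/ē_j < 1 for every consumer, hence a nonnegative solution exists
(a diagonally dominant M-matrix-like system) — the generator produces only
*valid* webs by construction rather than rejecting infeasible draws.

## 4. Sensitivity analyses

Two complementary checks of robustness:

1. **Fixed body masses** (`sensitivity_fixed_bodymass()`): every taxon's
   mass is replaced by its cross-mesocosm average (density-weighted by
   default, so mesocosms contributing more individuals weigh more;
   unweighted available). Re-running the pipeline shows how much of a
   treatment difference survives when within-taxon mass shifts are removed
   — what remains is attributable to compositional change. When a taxon's
   mass is already identical everywhere the averaging short-circuits to the
   exact stored value, making the no-variation case a bit-exact fixed point
   of the whole pipeline (floating-point averaging of identical values
   would otherwise introduce 1-ulp noise).
2. **Perturbation draws** (`sensitivity_perturb()`): mean-one lognormal
   multipliers with configurable coefficients of variation applied
   independently per population to biomass (via density) and metabolic
   loss, relaxing the steady-state premise; seeded, with per-draw
   aggregates and quantile summaries. The magnitudes are configuration
   (defaults cv = 0.1), since no canonical perturbation size exists.

## 5. The synthetic experiment generator

The generator emulates the reference design exactly: 6 blocks × 4 EcoUnits
× 4 mesocosms = 96 communities, soil history crossed with plant history
within every EcoUnit, one plant-richness level (1, 2, 3 or 6) per EcoUnit
with all four levels in every block.

The taxon pool (~30 taxa: 12 nematode, 10 mesofauna, 8 macrofauna) spans
masses 1e-4–1e2 mg so the mass-ratio feasibility curve is genuinely
exercised; nematodes carry fixed reference masses, mesofauna power-law
length regressions, macrofauna length–width regressions. Expected
abundances split class totals (2e5 nematodes, 8e3 mesofauna, 250
macrofauna per mesocosm — field-realistic orders of magnitude for temperate
grassland when scaled to a 0.2 m² surface) in proportion to mass^(−0.75),
the classic density–mass scaling.

Noise enters on the log scale: block intercepts (sd 0.15), EcoUnit
intercepts (sd 0.10), then mean-one lognormal abundance noise (cv 0.3) per
population and mean-one mass noise (cv 0.15). The nested intercepts give
the hierarchical bootstrap true structure to respect.

Treatment effects are *compositional by construction*: soil history
multiplies each taxon's expected abundance by `C·M^(−γ)`, with γ and C
solved (1-d root find plus a closed-form rescale) so that expected
community biomass is multiplied by `soil_biomass_multiplier` (default
exp(0.41)) and expected CWM body mass by `soil_cwm_multiplier` (default
exp(−0.64)). Within-taxon masses are never shifted by treatment — the
generator encodes assembly acting through composition (more small-bodied
taxa), not individual growth, which is also why the fixed-bodymass
sensitivity leaves its imposed effects essentially intact. Plant-history
and richness effects default to neutral.

What the generator does **not** emulate: taxon turnover between arms
(presence/absence), overdispersed counts beyond Poisson sampling,
correlated abundances among taxa, extraction inefficiency, measurement
rounding, or within-season dynamics. Passing recovery tests therefore shows
the estimators are consistent for the imposed effect under realistic noise
and nesting — not that field data meet these assumptions.

## 6. Contrasts and slopes

The reference analysis fits Bayesian hierarchical models and reads off
posterior contrasts; that machinery is off-the-shelf fitting, not a
methodological contribution, and this package replaces it with a defined
**hierarchical nonparametric bootstrap**: resample blocks with replacement,
then EcoUnits within each sampled block with replacement; recompute
treatment means (or OLS slopes) per draw from the resampled EcoUnits'
mesocosms; report percentile intervals at 95% and 90% and the
zero-exclusion decision (`clear` / `marginal` / `unclear`). Point estimates
come from the observed data, not the bootstrap mean. All six pairwise
contrasts of the four-level history factor are reported, plus pooled soil
and plant main contrasts (each history component averaged over the other),
which match how "with vs without soil history" differences are usually
quoted.

Choices worth making explicit:

* **Percentile vs HPD intervals**: bootstrap contrast distributions here
  are near-symmetric averages of many cells, so percentile and
  highest-density intervals practically coincide; percentile intervals are
  order-statistics-exact and need no density estimation.
* **Conservatism**: resampling *both* hierarchy levels inflates the
  variance of within-EcoUnit contrasts somewhat (block effects cancel in
  such contrasts, yet block resampling still contributes variance), so
  empirical null rejection runs at or below the nominal 5% — measured on
  generator nulls in the acceptance suite (200 replicates). We keep both
  levels because it is the honest scheme for between-EcoUnit questions and
  errs conservative for within-EcoUnit ones.
* **Log transform** defaults on for all flux/biomass/CWM responses: they
  are positive, right-skewed, and treatment effects are naturally
  multiplicative. Identity scale is a flag.
* **Slopes** (`structure_slopes()`) are log-log OLS slopes, by default
  *unstandardized* so that exact proportionality of flux to biomass yields
  slope 1 and elasticities read directly; `standardize = TRUE` z-scores
  predictors (once, on the full data, so draws stay comparable) when
  cross-predictor comparability matters more.
* n_boot defaults to 1000 (quantile granularity of 2.5% tails ≈ 25
  draws); the acceptance script uses 2000 for the single-experiment
  contrasts.

## 7. Problem sizes and reproducibility

Every stochastic routine takes an explicit seed and is reproducible from
it. The shipped test suite and acceptance script use: 1000 random webs of
≤ 30 nodes for the conservation and solver-agreement sweeps; one full
96-mesocosm synthetic experiment for end-to-end quantities; and 200
replicate experiments × 1000 bootstrap draws for the effect-recovery and
null-calibration rates — sizes at which the recovery/calibration
proportions have Monte-Carlo standard errors of ~1.5 percentage points,
comfortably inside the bands they are checked against.

## 8. Known limitations

* Trait values (diet fractions, link-model coefficients, metabolic
  constants) are inputs; the package validates and applies them but cannot
  audit their provenance.
* One temperature for all mesocosms; no seasonal or diel variation.
* The steady-state snapshot ignores transient dynamics; the perturbation
  sensitivity probes, but does not model, departures from it.
* Extraction efficiency is assumed complete for all samplers.
* Taxon-level resolution: cannibalism and within-taxon size structure are
  not representable.
* The bootstrap quantifies sampling uncertainty given the design; with six
  blocks, block-level resampling is coarse, which is visible as the
  conservative calibration noted above.
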