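---
title: "Methods: multi-species circuit-theory connectivity across climate scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-species circuit-theory connectivity across climate scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitshift)
```

## The problem

Climate change moves the places where species can live, and it moves them on
a schedule: land that connects today's populations may stop mattering by
mid-century, while land that is unremarkable today may become the corridor of
2090. Conservation planning therefore needs connectivity maps *per climate
scenario*, on a common scale, and a principled rule for deciding which land
belongs in a durable "connectivity network".

`circuitshift` implements that analysis end to end for any number of species
and three ordered climate scenarios (a current-climate reference plus two
future periods), entirely on rasters. Because the real inputs of such a study
(national occurrence archives, downscaled climate projections, landcover
surveys) are large and licensed, the package also ships a synthetic landscape
generator that reproduces the *statistical structure* those inputs have, so
the full pipeline runs, and is tested, from code alone.

## Pipeline and models

### 1. Occurrence data and suitability models

Occurrence records are thinned to one per grid cell (`grid_records`), and
pseudo-absences are drawn uniformly from cells holding no presence, three per
presence by default (`sample_pseudo_absences`). No exclusion buffer is used
beyond the presence cells themselves.

Cross-validation folds are *spatial*: records are assigned to hexagonal
blocks whose edge length starts at 1/20 of the square root of the study
extent's area and is rescaled within a four-fold range until roughly the
requested number of blocks (default 40) contain records; blocks are then
shuffled and dealt round-robin into five folds (`assign_spatial_blocks`).
Records in a block always share a fold, so evaluation measures spatial
transfer rather than interpolation between neighbouring records. The
rescaling range is deliberately bounded: if the records are so clustered
that too few blocks are occupied, the function reports that rather than
shrinking hexagons indefinitely, because folds built from micro-blocks
would defeat the purpose of spatial separation.

The native learner is a binomial GLM with logit link on linear (optionally
quadratic) predictor terms (`fit_logistic`), fitted by iteratively
reweighted least squares with convergence declared when the log-likelihood
changes by less than 1e-8 (at most 100 iterations). Perfect separation is
detected and refitted with a ridge penalty of 1e-6 so coefficients stay
finite; the learner carries a `separation` flag. Other learner families
(discriminant, tree-ensemble, maximum-entropy) are not reimplemented: any
model exposing the `new_learner` contract — a `predict` closure from a
predictor matrix to probabilities — can join an ensemble.

Each fold's learner is evaluated on its held-out block fold with ROC AUC
(rank/Mann–Whitney form, mid-rank tie correction) and the true skill
statistic, TSS = max over thresholds of (sensitivity + specificity − 1),
with the maximising threshold retained (`evaluate`). Members with held-out
AUC of at least 0.70 stay in the ensemble. The published rule says models
"scoring > 0.70" were kept; we read the boundary inclusively, which only
matters for a member sitting exactly on 0.70.

Projection uses committee averaging by default: each member's probability
map is binarised at that member's own best threshold (vote when probability
≥ threshold, a documented choice since the tie rule is conventionally left
unstated), and the surface is the fraction of members voting presence —
values on the lattice {0, 1/m, …, 1}. A TSS-weighted mean of raw
probabilities is available as `weighted_mean_ensemble`. Climate layers take
each scenario's values at projection time; distance-to-feature, topographic
position and landcover layers are held fixed across scenarios. A MESS-style
diagnostic (`mess_count`) reports, per cell, how many climate predictors
remain inside their training range — the count-of-in-range-variables map,
not the continuous similarity statistic.

### 2. Predictors

* `grid_distance` — distance to the nearest feature cell along the
  8-neighbour lattice (orthogonal step = cell size, diagonal = √2 × cell
  size), i.e. the eight-direction chamfer metric rather than straight-line
  Euclidean distance. Computed by repeated forward/backward chamfer sweeps
  to convergence; tests assert exact agreement with Dijkstra on the same
  weighted lattice.
* `tpi` — elevation minus the focal mean of a square window of side
  2r + 1, truncated at edges (a 250 m window at 50 m resolution is r = 2).
* `aggregate_raster` — block mean (continuous) or mode (categorical, ties
  to the smallest code) with nodata padding for non-divisible grids.
* `collinearity_filter` — a greedy scan in a caller-supplied ecological
  priority order, retaining a layer only if its absolute Pearson
  correlation with every retained layer is ≤ 0.70. The priority list makes
  the tie-break explicit, mirroring expert choice among correlated
  candidates. Correlations use listwise-complete cells; the pairwise
  alternative would use more data per pair but can produce an inconsistent
  correlation matrix, and the published screen does not say which was used.

### 3. Resistance

Suitability h ∈ [0, 1] maps to movement resistance by the
negative-exponential transform

R(h) = 100 − 99 · (1 − e^(−c·h)) / (1 − e^(−c)),

so R(0) = 100, R(1) = 1, strictly decreasing in h. The exponent magnitude c
comes from the canonical set {0.25, 0.5, 1, 2, 4, 8, 16, 32} and encodes
willingness to cross poor habitat: c = 0.25 is nearly linear (resistance
stays high except in excellent habitat — species reluctant to leave
suitable land), larger c collapses resistance at moderate suitability
(mobile species). As c → 0 the transform approaches the linear map
100 − 99h; resistance at fixed intermediate h is non-increasing in c. The
default species table assigns the three volant-but-habitat-bound birds
c = 2, the three wide-ranging mammals c = 4, and the remaining nine
species c = 0.25. The source study's counts for these groups total one
more than its species list; we keep the explicit per-species assignments
and let the remainder take 0.25, and every assignment is configurable.
The ceiling of 100 is itself a convention; nothing downstream depends on
it beyond the null normalisation, which is scale-free.

### 4. Circuit solves

The resistance raster becomes a resistor network: nodes are non-nodata
cells; each 8-neighbour pair carries conductance equal to the arithmetic
mean of the two cell conductances 1/R, divided by √2 on diagonals
(`build_lattice`). This is the standard raster circuit-model convention;
per-cell current is half the sum of absolute currents on incident edges,
except terminals, which carry the injected unit — so a straight series
chain reads the injected current at every cell.

Before solving, the surface is padded with a buffer of width
⌈fraction × max(rows, cols)⌉ (default fraction 0.20) filled by sampling
with replacement from the core's empirical resistance distribution
(`add_buffer`): terminals on a buffer keep node-placement artefacts out of
the study area, and the empirical fill avoids framing the landscape with
artificially cheap or expensive land. The published buffer rule gives a
width and a percentage without stating the base, so the fraction is
explicit configuration here. Terminals (default 25, hence 300 unordered
pairs) are placed evenly around the buffered perimeter from a seeded
rotational offset (`place_nodes`).

For each pair, one unit of current is injected and withdrawn and the
reduced graph-Laplacian system is solved; one sparse Cholesky factorisation
(grounding the first terminal) is shared by all pairs, each pair costing
two triangular solves. Per-cell currents accumulate over pairs
(`cumulative_current`). Correctness is enforced in tests against a dense
Laplacian pseudo-inverse oracle (≤ 12×12 grids, 1e-8), plus Kirchhoff
conservation, source–target reciprocity, invariance of currents under
global resistance scaling, and Rayleigh monotonicity.

Every species map is then divided, cell by cell, by the cumulative current
of an all-ones resistance surface with identical shape, nodata pattern and
terminals (`null_normalise`); the null is computed once per geometry and
reused across species. Uniform landscapes normalise to exactly 1 (currents
under fixed injection do not depend on the uniform resistance level), so
what survives is relative routing preference. The null uses uniform
resistance everywhere including the buffer — re-sampling the buffer in the
null would reintroduce the randomness the null exists to cancel. Cells
where the null current falls below 1e-12 become nodata rather than
produce unstable ratios. Finally `crop_buffer` restores the core extent.

### 5. Scenario comparison and the network

Normalised species maps are summed per scenario (`stack_species`). The
reference scenario's stacked surface supplies a mean x̄ and standard
deviation σ (population denominator N), and every scenario is expressed as
z = (x − x̄)/σ against those *reference* constants
(`relative_standardise`). The reference therefore reads mean 0, sd 1 by
construction, and a future cell's z is directly "so many present-day
standard deviations above the present-day average". N rather than N − 1
is used precisely so the reference sd is exactly 1; with raster-sized N
the distinction is cosmetic anyway. `summary_stats` reports min, max,
range, mean, sd, variance, skewness m₃/m₂^1.5 and *excess* kurtosis
m₄/m₂² − 3 (the raw-vs-excess convention is not fixed by the source
material; excess is declared here), and `surface_correlation` gives
inter-scenario Pearson r over jointly valid cells.

Each scenario's top decile — the ⌈0.1 N⌉ highest-z cells of that
scenario's own surface, ties broken by row-major order — forms a mask
(`top_decile_mask`), so all scenarios contribute the same amount of space.
`classify_network` applies the three-mask truth table: present in all
three periods = permanent; current + 2050 = early stepping stone;
2050 + 2090 = late stepping stone; any single period, *or current + 2090
without 2050*, = impermanent (a cell absent in 2050 cannot bridge the
century) and is excluded. Stepping stones are kept regardless of adjacency
to permanent cells — no contiguity filtering. The deciles are computed on
core-extent cells only; buffer cells never enter the network.

### 6. Zonal reporting

`rank_zones` ranks reporting zones by network area proportional to zone
area, with competition ("min") ranking so tied zones share a rank and the
following ranks are skipped — matching how the published zone table
reports ties. `protected_overlap` splits network area by a protection
mask; `landcover_tally` cross-tabulates network hectares by landcover
class and protection. Areas are cell counts × cell_size²/10⁴ hectares; no
polygon clipping is attempted because zone inputs are pre-rasterised.

## The synthetic landscape generator

`gen_climate_stack` builds each layer as Gaussian-smoothed white noise
(edge-truncated separable kernel, σ = 3 cells by default), rescaled to unit
variance, plus a unit north–south linear gradient: the simplest field with
controllable spatial autocorrelation and the latitudinal structure climate
layers have. Scenario change is an additive per-layer shift — warming
without re-simulating weather — so current and future stacks stay cell-wise
paired, as downscaled projections of one climate model family are.
`gen_landcover` cuts a smooth field at its quantiles (clumped, all classes
present); `gen_linear_features` rasterises boundary-to-boundary random
walks (each feature one 8-connected component); `gen_zones` is a Voronoi
partition around random seed cells; `gen_protected_mask` thresholds a
smooth field at its own quantile, giving blob-shaped patches at exact
coverage.

`gen_occurrences` samples presence cells without replacement with
probability proportional to a known logistic suitability
(`true_model`), one record per cell at the cell centre — so fitted models
can be tested for *parameter recovery*, not just internal consistency.
In the full simulated pipeline each species draws slope magnitudes
uniformly from [1.5, 3] with random signs, and its intercept is set so
suitable habitat (p > 0.5) covers about 15% of the landscape. Both
choices emulate the study conditions — habitat specialists with clear
environmental associations whose ensembles clear the ROC retention bar —
and they matter: a near-zero slope or a near-ubiquitous species gives a
presence/pseudo-absence design whose *Bayes-optimal* AUC sits below 0.7,
which no learner can beat.

What the generator does **not** emulate: real geography and coastline
shape, interactions among predictors, observation bias in occurrence
records, non-additive climate change, anisotropic movement. Passing tests
on synthetic data therefore demonstrate that the machinery computes what
it claims under known truth, not that any particular real landscape would
yield particular numbers.

## Numerical and design choices

* **Sparse solves.** The reduced Laplacian is SPD; `Matrix::Cholesky`
  (permuted, LL') factorises once per landscape, each of the 300 pair
  solves is two triangular solves. Grounding one terminal removes the
  Laplacian's null space.
* **Determinism.** Every stochastic step takes an explicit seed; the
  pipeline expands one global seed into per-stage, per-species sub-seeds
  with a fixed integer hashing rule (`derive_seed`), so stages can be
  re-run in isolation and whole runs are bit-reproducible (manifest
  checksums are asserted equal across reruns in the tests).
* **Ties.** Decile selection breaks ties by row-major order (a constant
  surface still yields ⌈0.1 N⌉ cells); aggregation mode ties go to the
  smallest class code; zone-rank ties share the minimum rank.
* **Degenerate inputs.** Constant reference surfaces (σ = 0) are an error
  for standardisation; single-class training or truth vectors are errors
  for fitting and evaluation; disconnected terminals name their
  components; an empty network warns and reports a protected fraction
  of 0.
* **Problem sizes.** The bundled tests and the acceptance script run the
  complete pipeline on 24–64-cell-wide landscapes with 2–3 species — sizes
  at which every stage, including the 300-pair solves and their null
  models, completes in seconds while exercising identical code paths to
  national-scale rasters.

## Worked example

```{r example, eval = FALSE}
plan <- experiment_plan(
  species = c(specialist = 0.25, bird = 2, mammal = 4),
  scenarios = c("current", "y2050", "y2090"),
  seed = 1,
  grid = list(n_rows = 48, n_cols = 48, n_layers = 3, cell_size = 1000),
  n_presence = 250, n_blocks = 30, n_folds = 5)
res <- run_pipeline(plan, out_dir = "connectivity_out")

res$stats_table          # per-scenario moments of the standardised surfaces
res$cor_table            # inter-scenario Pearson correlations
res$overlap              # network area inside/outside protection
head(res$zone_table)     # zones ranked by proportional network coverage
```

## Known limitations

* Rasters are in-memory matrices; national hectare-scale grids (10^8
  cells) need out-of-core storage and an iterative or multigrid solver,
  neither of which is attempted here.
* Only the logistic learner is native; ensemble diversity in the original
  multi-learner sense requires plugging in external models via
  `new_learner`.
* The chamfer distance is exact on obstacle-free grids; with nodata
  barriers it remains the converged sweep solution but large nodata mazes
  make repeated sweeps slow.
* No CRS handling: all rasters are assumed co-registered on one grid.
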