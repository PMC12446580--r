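# circuitshift

Multi-species, multi-scenario landscape connectivity from circuit theory,
in R.

## The problem

Conservation planners need to know which land keeps species populations
connected — not just today, but under the climates of 2050 and 2090, when
suitable habitat will have moved. `circuitshift` implements the full
analysis chain for that question:

1. **Habitat suitability** per species and climate scenario, from ensemble
   species distribution models: occurrence gridding, pseudo-absence
   sampling (3 per presence), hexagonal spatial-block cross-validation,
   logistic learners evaluated by TSS and ROC AUC, committee-average
   ensembling (members retained at held-out AUC ≥ 0.70).
2. **Resistance surfaces** by the negative-exponential transform
   `R(h) = 100 − 99·(1 − e^(−c·h))/(1 − e^(−c))`, with species-specific
   exponent magnitudes `c ∈ {0.25, 0.5, 1, 2, 4, 8, 16, 32}` encoding
   willingness to cross poor habitat (`R(0) = 100`, `R(1) = 1`).
3. **Omnidirectional circuit-theory current maps**: the resistance raster
   becomes an 8-neighbour resistor lattice (edge conductance = mean cell
   conductance, ÷√2 on diagonals); 25 terminals on a buffered perimeter
   give 300 pairwise sparse graph-Laplacian solves whose per-cell currents
   are accumulated, then divided by an all-ones null model to cancel
   geometry effects.
4. **Scenario standardisation**: species maps are stacked (summed) per
   scenario and expressed in z-units of the current-climate reference,
   `z = (x − x̄_ref)/σ_ref`, so the reference reads mean 0.00 / sd 1.00
   and futures read as departures from the contemporary average.
5. **The connectivity network**: each scenario's top decile of cells
   (⌈0.1·N⌉, own-surface threshold) is classified by the truth table —
   all three periods = *permanent*; current+2050 or 2050+2090 = *stepping
   stones*; single periods or current+2090 = *impermanent*, excluded —
   and the network is ranked by zone, split by protected areas, and
   tallied by landcover in hectares.

A synthetic landscape generator (smooth autocorrelated climate fields with
additive scenario shifts, clumped landcover, rasterised linear features,
occurrences sampled from a known logistic truth, Voronoi zones, blob
protected masks) makes the entire pipeline runnable and testable with no
external data.

## Worked example

Three simulated species (a sedentary specialist, `c = 0.25`; a bird,
`c = 2`; a mobile mammal, `c = 4`) on a 48 × 48 km landscape, three
scenarios:

```r
library(circuitshift)

plan <- experiment_plan(
  species   = c(specialist = 0.25, bird = 2, mammal = 4),
  scenarios = c("current", "y2050", "y2090"),
  seed      = 1,
  grid      = list(n_rows = 48, n_cols = 48, n_layers = 3, cell_size = 1000),
  n_presence = 250, n_blocks = 30, n_folds = 5)

res <- run_pipeline(plan, out_dir = "connectivity_out")

print(res$stats_table, digits = 3)
#>   statistic   current  y2050   y2090
#> 1       min -8.94e-01 -0.394  0.0757
#> 2       max  6.27e+00  3.638  4.7123
#> 3     range  7.16e+00  4.032  4.6366
#> 4      mean  7.47e-18  0.327  0.3359
#> 5        sd  1.00e+00  0.525  0.3297
#> 6  variance  1.00e+00  0.276  0.1087
#> 7  skewness  1.84e+00  2.416  3.9422
#> 8  kurtosis  3.60e+00  6.153 24.1912

print(res$cor_table, digits = 3)
#>         a     b pearson_r
#> 1 current y2050     0.565
#> 2 current y2090     0.453
#> 3   y2050 y2090     0.624

res$overlap$inside_fraction   # share of the network inside protection
#> [1] 0.0802

head(res$zone_table, 4)
#>   zone_id zone_area_ha network_area_ha proportion rank
#> 6       6        11500            3200     0.2783    1
#> 8       8        36000            6100     0.1694    2
#> 7       7        32100            3600     0.1121    3
#> 3       3        24100            2300     0.0954    4
```

Reading the output: the reference column standardises to mean 0 / sd 1 by
construction; the shrinking sd and rising skewness in the future columns
say connectivity becomes more diffuse (fewer extreme corridors) while a
long right tail of high-value land remains. The correlations quantify how
much the spatial pattern rearranges between periods. The zone table ranks
reporting zones by the share of their area inside the permanent +
stepping-stone network (competition ranking, ties share a rank), and
`res$overlap` reports how much of that network is currently protected.

Artefacts are written to `out_dir`: per-scenario stacked and standardised
surfaces plus the classified network as ESRI ASCII grids, the statistics /
correlation / zone / landcover tables as CSV, a JSON class legend, and a
`manifest.json` with seeds, run counts and per-file checksums (reruns with
the same seed are bit-identical).

A shell wrapper is included at `inst/cli/circuitshift.R`
(`simulate` and `all` subcommands) for use outside R sessions.

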