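# abindex

Museum specimen records are one of the few data sources that reach back
before modern surveys, but their raw counts confound a species' abundance
with where collectors happened to work. **abindex** turns georeferenced
natural history collection (NHC) occurrence records into effort-corrected
**abundance indices** and uses them to infer *population-level seasonal
movement* — the kind of month-to-month range shift that is nearly
impossible to observe directly for small migratory birds. It is written
for biodiversity informaticians and movement ecologists working with
Darwin-Core-style occurrence tables.

## The statistic

For focal species *k* in a spatial-temporal unit *r* (a grid cell, a
region, or a country, in a given month),

```
AI_kr = 100 * x_kr / sum_j x_jr
```

where `x_kr` is the number of focal specimens collected in *r* and the
denominator sums specimens of **all** species collected with comparable
methods there (for songbirds: all Passeriformes and Cuculiformes, plus
Picidae within Piciformes). The reference specimens act as a crude measure
of collecting effort, so `AI` tracks relative density where raw counts
track collectors.

On top of the index the package provides:

* **Movement tests** — four directional 2×2 Pearson chi-square tests
  (focal vs. other specimens × two strata) asking whether the focal
  population is enriched in the NW region during molt-stopover
  (July–October), in the S in winter (November–February, with and without
  an exclusion east of the Isthmus meridian at 94°W), in the NE during
  spring migration (March–April), and in lowlands (< 200 m) overall.
* **Greenness analysis** — mean Enhanced Vegetation Index (EVI) in 10 km
  buffers around collection sites, compared monthly against (A) uniformly
  random locations within the study boundary and (B) a 250-location
  weighted subsample of reference collecting sites, with Welch t-tests
  and 95% CIs. The two nulls discriminate habitat preference from
  collection bias toward productive places.
* **A synthetic-data generator** — collector-effort hotspots, a 12×3
  monthly regional occupancy model, EVI habitat preference and record
  corruption, so the entire chain can be validated against known truth.

## Worked example

Generate a synthetic study under the default quasi-circular movement
scenario (≈2,000 focal and ≈50,000 reference specimens sharing effort
hotspots) and run the analysis:

```r
library(abindex)

boundary <- synthetic_boundary()
rasters  <- generate_rasters(boundary = boundary, seed = 1)
scenario <- default_circular_scenario(seed = 1)
recs     <- generate_records(scenario, rasters = rasters, boundary = boundary)

ai <- ai_by_region(recs$focal, recs$reference)
ai_region_wide(ai)
#> # A tibble: 12 × 4
#>    month          NW    NE     S
#>  1 January    0.723  3.81  5.41
#>  2 February   0.786  2.87  4.67
#>  3 March      0.679  5.82  4.82
#>  4 April      0.241  5.19  3.79
#>  5 May        0.172  2.94  0.394
#>  6 June       0.0831 1.34  0.745
#>  7 July      12.8    3.56  0
#>  8 August    14.5    2.07  0.683
#>  9 September 14.8    0.763 0.705
#> 10 October    4.72   0.954 9.34
#> 11 November   1.08   3.06  8.53
#> 12 December   1.48   2.67  6.39
```

The index is the focal species' percentage share of comparably collected
specimens: the NW peak in July–September is the molt-stopover, the S
October onward is the wintering shift, and the NE loading in spring is
the Gulf-corridor return — the annual loop the scenario encodes. The
chi-square battery quantifies it:

```r
tidy(run_movement_battery(recs$focal, recs$reference))
#>   test                            statistic   p_value odds_ratio direction_consistent
#> 1 q1_molt_nw_vs_ne                     431. 1.22e- 95       7.22 TRUE
#> 2 q2_winter_s_vs_nw                    204. 3.14e- 46       6.45 TRUE
#> 3 q2_winter_s_vs_nw_excl_isthmus       196. 1.94e- 44       6.39 TRUE
#> 4 q3_spring_ne_vs_nw                   107. 3.62e- 25      12.8  TRUE
#> 5 q4_lowland_vs_upland                 767. 9.59e-169       4.39 TRUE
```

Each row is a focal-vs-other 2×2 table; `direction_consistent = TRUE`
means the odds ratio leans the way the movement hypothesis predicts, and
the p-values (Yates-corrected by default; both settings are reported)
show all four questions strongly confirmed. `run_evi_battery()` adds the
monthly greenness comparisons, `autoplot()` draws each result type, and
`run_pipeline()` / `make_fixture_bundle()` run the whole chain from a
YAML config (a thin CLI wrapper lives in `inst/cli/abindex.R`).

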