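---
title: "Abundance indices from collection records: models, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Abundance indices from collection records: models, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(abindex)
```

This vignette is the package's account of its science: the statistical
model behind each stage, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices made where the
method's published description leaves the design open.

## 1. The abundance index

Specimen counts from natural history collections confound density with
effort. The abundance index corrects the count of a focal species *k* in
unit *r* by the count of everything collected with similar methods there:

$$AI_{kr} = 100\,\frac{\chi_{kr}}{\sum_{j=1}^{n} \chi_{jr}}$$

`compute_ai()` applies this exactly. Three contracts matter:

* the denominator includes the focal species' own specimens (the sum runs
  over *all* species, the focal one among them). A flag
  (`include_focal = FALSE`) gives the sensitivity variant;
* a unit with zero total specimens has an **undefined** index, returned
  as `NA` — never zero, which would mean "searched and absent";
* per-cell tables only contain (cell, month) pairs with at least one
  focal specimen (an index is only mapped where the species was
  collected), while the regional 12 × 3 table is dense, with explicit
  zeros where reference collecting exists but the focal species is
  absent.

Region-level indices pool raw counts and then apply the formula. A pooled
ratio is not a mean of cell ratios; the test suite carries a constructed
counterexample so nobody "simplifies" this later.

## 2. Spatial frame

Records are assigned to a 5-arc-minute grid whose cell edges are anchored
at integer degrees from (0°, −120°W). The anchoring is a reproducibility
decision: any fixed origin works, but it must be stated. Cells are
half-open `[edge, edge + size)` south/west-closed, so every in-extent
point belongs to exactly one cell. The regional partition is defined on
raw coordinates, not cells: S below 20°N; the northern band splits at
103°W into NW and NE. Boundary ties go north/east (a point exactly on
20°N is NW/NE; exactly on 103°W is NE). Seasonal periods follow the focal
species' annual cycle — molt-stopover July–October, winter
November–February, spring migration March–April; May and June belong to
no period. Elevation classifies from the record's own field (lowland
< 200 m ≤ upland); no DEM lookup is attempted, and elevation-unknown
records are excluded only from the elevation question.

## 3. Movement tests

Each question is a 2 × 2 Pearson chi-square: rows are focal vs. *other*
reference specimens (here the focal rows are removed from the reference
set — unlike the index denominator, the two rows must be disjoint),
columns two disjoint strata (two regions, or two elevation classes). The
four questions: NW vs. NE in molt; S vs. NW in winter (also re-run
excluding records east of 94°W, guarding against an unrelated population
wintering on the eastern peninsula); NE vs. NW in spring; lowland vs.
upland over all months pooled (the elevation hypothesis has no stated
season).

Numerical choices:

* Continuity correction defaults **on** (the conventional default for
  2 × 2 tables in R, the environment this style of analysis is normally
  run in); both the Pearson and Yates statistics are always reported, so
  the choice is visible rather than buried.
* P-values are two-sided; the directional prediction is reported
  separately as `direction_consistent`, true when the observed odds
  ratio exceeds 1 with the predicted-high stratum first. This mirrors
  how such tests are conventionally reported.
* No multiple-testing adjustment is applied; the output records the
  family size (4 questions) so a reader can apply one.
* A table with an empty margin is flagged invalid and no statistic is
  produced; the battery continues with the remaining questions.

## 4. Greenness (EVI) analysis

For each month, the mean EVI within a 10 km buffer of each collection
site is compared against two nulls:

* **A — random locations.** `n_random` (default 500) points uniform over
  the study polygon, drawn once and reused across months.
* **B — reference subsample.** 250 locations per month drawn from the
  *reference* collecting sites, after rounding coordinates to the nearest
  0.01° (~1 km); each surviving location's mean is duplicated by the
  number of specimens collected there that month. B asks "do focal birds
  sit in greener places *than collecting effort generally does*", which
  cancels collection bias toward productive sites; A asks the absolute
  question and inherits that bias.

Buffer membership uses great-circle (haversine) distance to **pixel
centers** — the geodesic choice is correct at continental latitudes, and
the center rule keeps counts integer-consistent with the closed-form
oracle `πr² / pixel area`, about 10–12 pixels at 0.05° resolution between
15° and 30°N. No-data pixels (water) are dropped; locations with fewer
than 3 valid pixels are filtered from the reference subsample *and* the
specimen side (specimen-site pixel counts then range ≥ 3, matching how
such data are reported), while random locations are kept unfiltered by
default (`filter_random` applies the filter symmetrically for sensitivity
analysis). The t-test is Welch (unequal variances) by default with a
pooled-variance flag; specimen values enter once per specimen via the
location weights. Degenerate months (either side < 2 values) are marked
not computable rather than erroring; two identical constant sides give
t = 0, p = 1.

Rasters are a minimal in-package container (matrix + extent) with
plain-text ESRI ASCII grid I/O — single-band geographic grids are an
acquisition detail, not methodology, and this keeps the pipeline free of
heavyweight geospatial dependencies. Point-in-polygon is an even-odd ray
cast; random points come from rejection sampling in the bounding box and
are bit-reproducible under a seed.

## 5. The synthetic generator

The generator exists so every stage can be tested against known truth; it
emulates the statistical structure the analysis assumes, not bunting
demography.

* **Effort hotspots.** Collecting effort is a Gaussian mixture of seven
  synthetic localities with unequal weights, shared between focal and
  reference generation. Sharing is the point: it makes raw counts
  effort-confounded while leaving the index identifiable — exactly the
  bias the method claims to correct, so the test suite demonstrates that
  claim directly.
* **Shared collecting sites.** Each month draws a discrete pool of
  collecting sites from the mixture (about one site per four expected
  records, floor 200) and both datasets sample records from that pool.
  Collectors revisit localities, so real data carry heavy locality
  multiplicity — needed for the subsample weighting — and under a null
  scenario the focal and other rows become exchangeable draws from the
  same site distribution, which keeps the chi-square tests calibrated.
* **Occupancy as multipliers.** The 12 × 3 occupancy matrix multiplies
  the reference effort mass per region rather than setting absolute
  region probabilities. A matrix of ones therefore reproduces "focal
  distributed proportionally to reference" exactly (the type-I-error
  condition), and the recovered regional index pattern mirrors the
  multipliers, which makes end-to-end recovery tests interpretable.
  Monthly totals are Poisson with intensity proportional to occupancy
  row sums.
* **Greenness surface.** Monthly EVI = base 0.35 − 0.012/° latitude
  gradient + a fixed mesoscale mosaic (amplitude 0.25, wavelength 3°,
  the few-degree coastal-forest/interior-dryland heterogeneity real
  greenness maps show) + regional seasonal cosines (NW amplitude 0.15
  peaking in September — the monsoon; NE 0.08 peaking in April; S 0.10
  peaking in October) + N(0, 0.03) pixel noise, clipped to [−0.2, 1].
  Without the mosaic term the surface is so flat that any plausible
  habitat selection is undetectable — flatness would be a property of the
  test bed, not of the method.
* **Habitat preference and collection bias.** Focal sites are tilted by
  `exp(β·EVI)` with β = 4 per EVI unit in the default circular scenario
  (odds ≈ 7:1 between mosaic-high and mosaic-low habitat — strong but
  plausible selection); `reference_evi_beta` applies the same tilt to
  reference collecting to emulate collectors favouring productive sites.
* **Corruption.** A configurable fraction of rows is damaged (missing
  month, latitude 95, the (0,0) "null island", missing longitude), with
  the damaged indices recorded so cleaning can be checked for exactness.
* **The default circular scenario** encodes the annual loop: NW-loaded
  July–September (S empty in July), S-loaded October–April, NE loaded in
  late winter and spring, with May–June intensity low (most of the
  population off the study area), 2,000 expected focal and 50,000
  expected reference records, lowland fraction 0.8 vs. 0.5.

What the generator does **not** emulate: taxonomic misidentification,
georeferencing error smaller than outright corruption, temporal trends
across the pooled years, spatial autocorrelation of records beyond the
hotspot scale, or real coastlines (the boundary is a synthetic polygon).
Passing tests therefore show the pipeline recovers the signals it is
designed for under its stated assumptions — not that any particular real
dataset satisfies those assumptions.

## 6. Cleaning rules

The published description of record cleaning ("missing or obviously
erroneous date or coordinate values") leaves "obviously erroneous"
undefined. The package's reproducible proxy: a record is dropped by the
first failing rule among (1) missing month, (2) missing latitude or
longitude, (3) coordinates out of range, exactly (0, 0), or — optionally,
off by default — outside the supplied boundary polygon. Day and year are
*not* required: the analysis is monthly and pools all years. The
cleaning report accounts for every input record exactly once and
cleaning is idempotent.

## 7. Problem sizes used by the test and acceptance suites

Chosen as the package's own validation design: formula and oracle checks
run on 100–200 random tables; movement-signal recovery uses 50–100
replicates of the full-size circular scenario (≈2,000/50,000); type-I
calibration uses 500–1,000 replicates at 600 focal / 6,000 reference
records (large enough for the asymptotic test, small enough to replicate
heavily); greenness power uses 250 values per side per month at 0.05°
raster resolution, calibration 1,000 resampled replicates from a
precomputed pool of uniform-location buffer means, and the effort-bias
demonstration 10 seeded replicates with a deliberately south-skewed
effort mixture. Observed behaviour at these sizes: recovery in ≥ 95% of
replicates at p < 0.005, null rejection within 2.5–7.5% at α = 0.05, and
every occupied month detected at p < 0.01 under β = 4.

## 8. Known limitations

* The index corrects effort only as finely as the reference taxa share
  collecting methods with the focal species; a reference set collected
  differently re-introduces bias (the package exposes the filter so this
  is an explicit analyst decision).
* Chi-square questions are population-level; they say nothing about
  individual movement, and a "movement" signature is indistinguishable
  from regionally staggered sedentary populations without outside
  evidence.
* Elevation relies on record-supplied values; records lacking them are
  silently absent from that one question.
* The greenness comparison A inherits any spatial bias of collecting
  effort; only the A-vs-B contrast, not A alone, speaks to habitat
  preference.
* Boundary-tie conventions (20°N, 103°W, 200 m) are package decisions;
  analyses at other conventions require re-running with a different
  `region_partition()`.
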