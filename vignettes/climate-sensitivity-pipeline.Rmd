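---
title: "Assessing climate sensitivity of species distributions with climsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing climate sensitivity of species distributions with climsens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climsens)
```

## The problem

Large volunteer survey programs — breeding-season roadside counts and
early-winter count circles — provide decades of presence/absence records
for hundreds of bird species across a continent. Coupled with monthly
climate grids, such records support correlative species distribution
models (SDMs) that map each species' climatic suitability, project it
under future emissions scenarios, and summarize how much of the current
range is expected to remain climatically suitable and how much new area
could become suitable. From those two quantities a species can be placed
into a simple climate sensitivity vocabulary — *climate endangered*,
*climate threatened*, or *climate stable* — that conservation planners
can act on.

`climsens` implements that entire assessment as a reusable, testable
pipeline. Because the original survey and climate data are large,
access-restricted, or both, the package ships a synthetic-data generator
that produces landscapes, climates, virtual species and survey records
with *exact ground truth*, so every stage — and the pipeline as a whole
— can be validated against known answers.

## The model chain and its assumptions

### Occurrence model

Each species-season is modeled with boosted regression trees (gradient
boosted classification trees, Bernoulli loss). Defaults follow the
standard large-survey SDM protocol: learning rate 0.01, tree complexity
(interaction depth) 5, 10-fold cross-validation to select the number of
trees, a suggested minimum of 1000 trees, bag fraction 0.5. Covariates
are the 19 standard bioclimatic variables plus one survey covariate:
party-hours of effort for non-breeding (count-circle) records, ordinal
date for breeding (route) records. Effort and timing enter the model as
ordinary covariates rather than through a detection layer; occupancy
models were deliberately avoided because multi-decade volunteer data
violate closure assumptions, and effort-as-covariate produces
effort-adjusted predictions directly. When projecting over a grid, the
survey covariate is fixed at its training median as a uniform constant
layer.

The booster backend is `xgboost`, configured to those settings; the
model contract (probabilistic classifier over a covariate frame) is
backend-agnostic and the evaluation suite never inspects booster
internals.

### Bioclimatic variables

`compute_bioclim()` derives BIO1–BIO19 from monthly minimum temperature,
maximum temperature and precipitation. Monthly mean temperature is
`(tmin + tmax)/2`; "quarters" are the twelve wrap-around consecutive
three-month windows, ties broken by earliest start, matching the
dominant SDM toolchain. Two conventions worth noting: BIO4 is the
standard deviation of monthly means × 100, and BIO15 divides the
monthly-precipitation standard deviation by (mean + 1) to stay defined
in fully arid cells. All 19 variables are computed; analyses that use a
subset (some published assessments used 17, without enumerating which)
can pass any subset via the configuration — a superset is safe.

### Future climates: the anomaly (delta) method

`delta_downscale()` builds each future fine-scale climate as
*fine baseline + (coarse future − coarse reference)* per month and
variable, with nearest-cell resampling of the anomaly and a floor of
zero on precipitation. Anomalies are additive for every variable,
exactly mirroring the subtract-then-add construction; the *generator*,
by contrast, perturbs its synthetic future precipitation
multiplicatively, which is the conventional way to synthesize scenario
drying without creating negative rainfall. Per-GCM structure is
emulated as a spatially smooth, mean-zero temperature jitter field
added to the uniform scenario warming.

### Range delineation and consensus forecasting

Continuous projections are converted to binary ranges at the threshold
maximizing Cohen's Kappa against the training observations
(`max_kappa_threshold()`), a conservative choice for rare species. Ties
are broken toward the *smallest* threshold, again the conservative
(larger-range) direction. One threshold is fitted per species-season on
current-period data and reused for every projection: recomputing
thresholds in the future would require future observations, which do
not exist. Projections from multiple GCMs within one scenario × period
are ensembled by the cell-wise mean of suitabilities *before*
thresholding (consensus forecasting); majority-vote-after-thresholding
is a documented alternative the API can express but is not the default.

### Sensitivity categories

For current range `C` and future range `F` on one grid:
stability `S = |C ∩ F| / |C|`, loss `L = 1 − S`, and potential
expansion `E = |F \ C| / |C|` (never truncated internally; truncation
at 1 is purely a plotting convention). The categories, evaluated over
the scenario set:

* **endangered** — `L(2050) > 0.5` *and* `E(2050) < L(2050)` in **all**
  scenarios;
* **threatened** — otherwise `L(2080) > 0.5` in **all** scenarios;
* **stable** — otherwise;
* **other** — introduced or range-marginal species, regardless of
  projections.

Two reading choices deserve mention. The "no net gain" clause of the
endangered definition is operationalized as `E < L` *at 2050, per
scenario* — the most precise published statement of the rule — rather
than at 2080. And loss comparisons are strict (`> 0.5`), so a species
at exactly 50% loss is stable. Single-scenario columns of the category
table apply the same cascade to one scenario's trajectory. Seasonal
categories combine by severity (endangered > threatened > stable), with
the one-season/both-seasons distinction retained.

### Downstream summaries

* **Centroid shifts** — latitude, elevation and coast distance are
  averaged over range cells with equal weights (each cell's share of the
  binary range); a suitability-weighted variant is available via the
  `weights` argument. Latitude differences convert to km at 111.32
  km/degree, with no `cos(latitude)` area weighting since the analysis
  grid is an equal-area-like 10 × 10 km grid.
* **Community turnover** — per-cell binary Bray–Curtis dissimilarity
  (1 − Sørensen). A cell empty in both periods is defined 0 and
  excluded from the study-area mean.
* **Rank correlations** — climate categories and conservation-priority
  schemes are converted to ranks with 1 = highest threat everywhere.
  Because PIF-style scores *rise* with threat while the other schemes
  fall, PIF scores are negated before correlation; Kendall's tau is
  computed as tau-b (tie-corrected), the appropriate variant for
  heavily tied 3-level ordinals, with a tie-adjusted normal
  approximation for the p-value.
* **Variance components** — REML random-intercept models (via `lme4`)
  decompose variance in stability or relative range change into species,
  archetype/strategy and scenario components plus residual; negative
  estimates truncate at zero and proportions sum to one.

## What the synthetic generator emulates

`make_landscape()` builds a grid with a straight western coastline,
linearly increasing latitude, and a smooth autocorrelated elevation
field. `make_baseline_climate()` composes temperature from a
latitudinal gradient (−0.7 °C/°N), the standard environmental lapse
rate (−6.5 °C/km), a seasonal sinusoid peaking in July, and small
noise; precipitation declines linearly inland from the coast. Warming
trajectories by scenario (°C at 2020/2050/2080: A2 0.8/1.8/3.6, A1B
0.7/1.6/3.0, B2 0.5/1.1/2.4) follow the high/mid/low scenario families
with the characteristic late-century acceleration — by 2080 warming is
roughly twice the mid-century value — and are monotone within scenario.

Virtual species respond to annual mean temperature through independent
Gaussian niches, in three archetypes whose fate under warming is known
by construction. Writing `w = σ√(2 ln 2)` for the half-width of the
suitable band at half the peak (the truth-range threshold) and
approximating cells as uniform over the climate gradient, the expected
loss under a uniform warming Δ is ≈ Δ/(2w):

* **shrinkers** (σ ∈ [0.5, 0.65], optimum at the 5th–10th percentile of
  the cell climate) lose ≈ 0.7–0.9 of their range by 2050 even under
  B2, with almost no colder cells to colonize → endangered;
* **shifters** (σ ∈ [1.55, 1.65], optimum mid-gradient) lose ≈ 0.3 by
  2050 under B2 (blocking the endangered rule with margin) but ≈ 0.62–
  0.66 by 2080 in every scenario → threatened, their band translating
  poleward;
* **stable** species (σ ∈ [5, 7]) lose < 0.35 everywhere.

These breadths were chosen from that closed-form geometry so each
archetype sits well away from the 0.5 classification boundaries,
leaving room for the ±20–25% effective-bandwidth error that separates
estimated ranges from true ones.

Detection is conflated with occupancy into a single Bernoulli
probability: non-breeding surveys detect with the saturating form
`1 − exp(−β · effort)` (β defaults to 0.25/h, ≈ 0.92 detection at the
~10 h median effort), breeding surveys with a Gaussian window in
ordinal date (peak day 160, sd 30). The saturating-exponential is a
stand-in — no published functional form links party-hours to detection
— and is isolated behind the `detect_beta` parameter.

What the generator does **not** emulate: route/stop substructure of
breeding surveys, count-circle geometry, abundance, observer turnover,
spatial sampling bias, land cover, biotic interactions, and dispersal
limits on colonizing "potential" range. Passing tests on synthetic data
therefore demonstrate that the *pipeline machinery* is correct and that
the category rules recover known truth under realistic sampling noise —
not that any particular real-world assessment is accurate.

## Numerical choices and degenerate inputs

* Kappa with both margins single-class (`p_e = 1`) is defined 0.
* Max-Kappa threshold candidates are exactly the unique predicted
  values; ties broken to the smallest threshold.
* AUC uses mid-ranks for ties (exact Mann–Whitney correspondence).
* Empty current ranges make stability/expansion undefined — an error,
  since such a species is unmodelable, not "stable".
* Bray–Curtis for two empty communities is 0 and excluded from means.
* Variance-component factors with fewer than two levels are dropped
  with a warning; a constant response short-circuits to residual = 1.
* The model QC rule (drop models whose AUC or deviance explained falls
  more than 2 SD below the across-species mean) is one-sided — quality
  can only be violated downward — and the zero-spread case keeps all.
  In the synthetic experiment QC results are recorded but flagged
  species are still classified, so truth recovery is assessed over the
  full cohort.

## The reference experiment

`default_config()` encodes the reference study conditions: a 100 × 100
grid of 10 km cells, 500 survey sites visited with probability 0.3 per
year over training years 2000–2009 and test years 1990–1999, 30 species
in equal archetype thirds (plus 2 introduced and 1 marginal flagged
"other"), 3 scenarios × 3 periods × 3 GCMs (9 consensus projections per
species), and the standard BRT settings. One full run takes a few
minutes on a single CPU; all randomness derives from the single master
seed, and repeated runs are bit-identical.

```{r, eval = FALSE}
run <- run_end_to_end(default_config(seed = 1), outdir = "run1")
run$recovery            # fraction of species assigned their true category
run$table1              # season x scenario category counts
head(run$species_summary)
```

`scripts/acceptance.R` reruns exactly this experiment from scratch and
writes the headline quantities (category counts, truth recovery, AUC,
turnover, shifts, variance shares, rank correlations) as JSON.

## Re-deriving published headline numbers

`reproduce_published()` applies the classifier to a CSV export of a
per-species range-change appendix (loss and relative range-size change
per scenario × period) and the rank-correlation analysis to a
conservation-status appendix, reporting computed counts and
correlations side by side with any published reference values supplied.
The package does not redistribute such appendices; see
`inst/extdata/supplementary/README.md` for the expected layout. Two
documented ambiguities can affect third-decimal agreement when
comparing against published tables: whether the endangered gain clause
also inspects 2080, and whether published Kendall correlations used
tau-a or tau-b (this package reports tau-b; both are cheap to compute
from the returned records).

## Known limitations

* The anomaly method assumes additive transfer of coarse-model change
  onto the fine baseline; no quantile mapping is offered.
* Nearest-cell extraction and resampling only — appropriate at the
  10–24 km mismatch tolerance of the source surveys, but not for
  sub-cell precision.
* No reprojection between coordinate reference systems; the synthetic
  landscape is a plane with a linear latitude axis.
* Thresholds are transferred unchanged to future projections; any
  calibration drift in projected probabilities maps directly into range
  size.
* "Potential expansion" ignores dispersal feasibility by construction.
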