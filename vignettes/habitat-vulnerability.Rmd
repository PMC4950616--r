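---
title: "Assessing habitat vulnerability to climate change with ensemble SDMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing habitat vulnerability to climate change with ensemble SDMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeshift)
```

## The problem

Forest managers planning for the end of the century need to know *where*,
within a species' present range, climatic conditions are likely to become
unsuitable. treeshift implements the full chain of a habitat-suitability
vulnerability assessment on a regular grid of analysis cells (by default
20 x 20 km, 400 km² each): species distribution models are calibrated on
presence/absence and environmental predictors under baseline climate,
projected under an ensemble of future climate simulations, combined into a
consensus probability surface, binarized, and finally every cell of the
species' baseline range is classified as **unsuitable habitat (UH)**,
**less suitable habitat (LSH)** or **persistent habitat (PH)**, with a
per-cell **agreement value** quantifying how many of the single projections
support the consensus verdict, and regional roll-ups of areas and shares.

Because the forest-inventory and climate-model data behind such studies are
large and proprietary, the package ships a synthetic-landscape generator
with *known ground truth*: every downstream stage can be exercised,
end to end, against a virtual species whose true suitability surface is
available for comparison.

## The model

### Predictors

Three bioclimatic variables are derived from monthly normals
(`derive_climate_variables()`):

* `TEM` — annual mean temperature (°C), the mean of the 12 monthly means;
* `PRE` — annual total precipitation (mm), the sum of the 12 monthly totals;
* `PRATIO` — the "useful precipitation" fraction, the June–September
  precipitation sum divided by `PRE` (dimensionless, in [0, 1]; undefined
  and flagged `NA` when `PRE` = 0).

These three are themselves the product of a variable-reduction step:
candidate climate variables tend to be highly collinear, so
`cluster_select_predictors()` groups them by average-linkage hierarchical
clustering on the dissimilarity 1 − |r| and keeps, per cluster, the variable
most correlated with its own group. Elevation and compositional edaphic
fractions complete the predictor set; one edaphic fraction is dropped for
model fitting since the fractions sum to one.

### Future climate: the change-field method

Future monthly climate is obtained by the change-field (delta) method
(`delta_downscale()`): each climate simulation supplies monthly anomalies
(future run minus baseline run) on its own coarse grid (~250-km cells);
these deltas are interpolated to the analysis-cell centroids with linear
triangle-based (Delaunay barycentric) interpolation and *added* to the
observed baseline normals. Interpolation is exact for constant and linear
anomaly fields and passes coarse-centroid values through unchanged at
coincident points; analysis cells outside the convex hull of the coarse
centroids take the nearest centroid's delta. Precipitation deltas are
applied additively in mm, and any negative future monthly precipitation is
clamped to zero with a logged count — the additive convention keeps one
code path for both variables, with relative precipitation targets converted
to mm when the synthetic ensemble is generated.

Running every model under every available simulation is wasteful; instead
`select_scenarios()` standardizes the per-simulation domain-averaged annual
anomalies (ΔTEM, ΔPRE, ΔPRATIO), clusters them by k-means (25 restarts,
fixed seed) and keeps the simulation nearest each cluster centroid — 7 of
70 under the default configuration — treating the retained set as
equiprobable.

### The ensemble and its consensus

`fit_sdm_ensemble()` calibrates eight modelling techniques — GLM with
quadratic terms and stepwise AIC selection, GAM with ~3-df smooths, an
adaptive piecewise-linear (hinge-basis, lasso-selected) regression in the
MARS family, a classification tree, Gaussian mixture discriminant analysis,
a single-hidden-layer neural network with five-fold cross-validated weight
decay, gradient-boosted trees capped at 2,000 trees with early stopping,
and a random forest — on each of 10 random 70/30 split-sample partitions
(calibration size = round-half-up of 0.7 n, so 6,418 cells split into
4,493/1,925). That is 80 models per species; projected under 7 simulations
they yield 560 future probability layers.

Each model's held-out AUC — the Mann–Whitney rank statistic, i.e. the
probability that a random presence outranks a random absence, ties counted
one half — becomes its weight in the consensus:

$$\mathrm{WAP}_{i,\mathrm{baseline}} =
  \frac{\sum_{j}\sum_{k} \mathrm{AUC}_{jk}\, P_{ijk}}
       {\sum_{j}\sum_{k} \mathrm{AUC}_{jk}},
\qquad
\mathrm{WAP}_{i,2080} =
  \frac{\sum_{j}\sum_{k}\sum_{l} \mathrm{AUC}_{jk}\, P_{ijkl}}
       {L \sum_{j}\sum_{k} \mathrm{AUC}_{jk}},$$

with $i$ the cell, $j$ the technique, $k$ the repetition, $l$ the
simulation and $L$ the simulation count. Weights are used raw (no
rescaling or thresholding); a model that fails to fit is retried once under
a perturbed seed and then excluded, which shrinks numerator and denominator
symmetrically.

### Binarization and classification

A single threshold, reused for baseline and future, is chosen by exhaustive
scan over the distinct consensus probabilities as the value that jointly
maximizes sensitivity + specificity against observed occurrence
(`select_threshold()`; ties break toward the smallest candidate). The
species' **baseline range** is every cell with
$\mathrm{WAP}_{\mathrm{baseline}} \ge$ threshold. Within it
(`classify_cells()`):

* **UH** — $\mathrm{WAP}_{2080} <$ threshold (suitability is lost);
* **LSH** — still suitable, but
  $\mathrm{WAP}_{2080} - \mathrm{WAP}_{\mathrm{baseline}} < 0$ and
  $|\Delta \mathrm{WAP}| \ge 0.15$;
* **PH** — still suitable with a smaller decline, or no decline.

The 0.15 change threshold is an *absolute* probability difference, and the
boundary case $|\Delta\mathrm{WAP}| = 0.15$ is LSH (the rule uses ≥).
Cells outside the baseline range are tracked as GAINED (future probability
reaches the threshold) or OUTSIDE_BASELINE and excluded from vulnerability
statistics, which deliberately emphasize loss over opportunity.

One textual subtlety: the source description of the common threshold can be
read as matching occupancy against the *future* consensus. Observed
occurrence reflects baseline climate, so the package defaults to the
baseline consensus (`threshold_basis = "baseline"`), while
`threshold_basis = "future"` preserves the literal alternative.

### Agreement, regions, overlay, uncertainty

The **agreement value** of a baseline-range cell is the percentage of the
single projections (each future layer $P_{ijkl}$ classified against its own
baseline layer $P_{ijk}$ under identical rules) whose category matches the
consensus category. "Agreement with the average projection" admits more
than one operationalization; the package's default is this three-way
categorical agreement, with a documented `mode = "binary"` alternative that
compares only the suitable/unsuitable outcome. Agreement bands ≤ 50%
(poor), 50–75% (medium) and > 75% (high) are emitted as labels.
`summarize_by_region()` reports, per reporting region and overall, the area
(cells × 400 km²), share of the regional baseline range, and the unweighted
mean agreement per category (all cells have equal area) — regional means
are computed within each region-category, so both restricted and overall
denominators are available. `risk_overlay()` counts, on cells suitable for
*all* species at baseline, how many species are classified UH or LSH.

`sensitivity_analysis()` sweeps the change threshold from 0.05 to 0.25: the
UH share is invariant by construction (and asserted), while the LSH share
is non-increasing, the displaced cells moving to PH.
`partition_uncertainty()` relates all future probabilities to the three
uncertainty factors — data split, technique, simulation — through a
main-effects ANOVA over the full factorial cube and reports each factor's
explained-sum-of-squares ratio against the total; the balanced design makes
the decomposition order-independent, with cell-to-cell variation and
interactions left in the residual.

## The synthetic world

`generate_landscape()` emulates a northeastern-North-America modelling
domain: a strong latitudinal temperature gradient (−1.1 °C per degree
latitude by default, annual means running from +20 °C at the southern edge
to below −5 °C in the north), a weaker precipitation gradient (annual
totals ~1,100 mm south to ~850 mm north), a ±16 °C seasonal cycle peaking
in July, summer-weighted precipitation seasonality, elevation as a smooth
random surface with a northward trend capped at 1,250 m (lapse −6.5 °C/km),
compositional edaphic fractions drawn from latitude-modulated Dirichlet
concentrations, and reporting regions as five equal-width latitude bands —
the synthetic stand-ins for bioclimatic domains. The default grid is
50 × 40 = 2,000 cells, roughly a third of a full provincial grid, chosen so
a complete run stays interactive; any size down to 2 × 2 is accepted.

A virtual species (`species_response()`) is a logistic response on
standardized predictors: linear and quadratic terms in TEM, PRE, PRATIO and
elevation, linear terms on the edaphic fractions. `generate_occurrence()`
freezes the landscape's standardization into the response, optionally
shifts the intercept so the mean true probability matches a prevalence
target exactly (monotone root finding), and draws occurrence as independent
Bernoulli trials — returning both the draw and the truth so recovery can be
measured. `generate_simulation_ensemble()` produces per-simulation monthly
anomaly fields on a coarse (250-km) lattice: across the ensemble the
domain-mean annual anomalies span exactly +1.9 to +8 °C of warming and +3%
to +26% of precipitation (evenly spread, independently permuted), each
simulation carrying a winter-amplified seasonal warming profile and a
smooth zero-mean spatial pattern that varies only at coarse-grid scale.

What the generator does *not* emulate: terrain/climate physics, spatial
autocorrelation of occurrence beyond the smooth environmental surfaces,
observation error in presence/absence, and real soil taxonomy. Passing
recovery tests therefore demonstrate that the pipeline's inference machinery
is sound under its own assumptions, not that any particular real species
would be modelled this well.

## Numerical choices and degenerate inputs

* Calibration-set size uses round-half-up, not banker's rounding.
* AUC ties count one half; a single observed class yields a flagged `NA`,
  never an error deep inside a fit.
* The threshold scan is exhaustive over distinct probabilities and scores
  candidates in exact integer arithmetic (TP·n₀ + TN·n₁), so tied optima
  resolve deterministically to the smallest candidate regardless of
  floating-point rounding; an all-equal probability vector is flagged
  degenerate and returns that value.
* `PRATIO` with zero annual precipitation is a flagged missing value.
* Fewer than 3 coarse centroids is an error; collinear centroids fall back
  to nearest-centroid deltas with one warning per downscale call.
* Negative future monthly precipitation is clamped to zero with a count.
* All randomness flows from one master seed through a deterministic
  per-stage/per-unit splitting scheme (`run_pipeline()` manifests record
  the seed and the MD5 digest of every artifact; re-running a configuration
  reproduces identical digests, which the test suite asserts).
* k-means scenario selection standardizes features column-wise; a constant
  anomaly column contributes zero rather than dividing by zero.

## Design choices where the design was open

* **Technique roster.** MARS and mixture discriminant analysis are
  represented by their nearest well-supported equivalents (hinge-basis
  lasso-selected regression; Gaussian mixture discriminant analysis via
  model-based clustering), and boosting by gradient-boosted trees with the
  2,000-tree cap. The ensemble contract is only that techniques be
  distinct families emitting probabilities weightable by AUC; adapters are
  self-contained and swappable.
* **Predictor clustering** replaces oblique principal-component clustering
  with agglomerative clustering on 1 − |r|, which has the same stated goal
  and a standard open implementation; its behaviour is pinned by tests.
* **AUC weights** are indexed per (technique, repetition) model, not
  averaged per technique.
* **Agreement** defaults to three-way categorical agreement (see above).
* **Threshold basis** defaults to the baseline consensus (see above).
* **Extrapolation** outside the coarse hull is nearest-centroid.

## Problem sizes used by the shipped checks

The package's own verification runs use a 2,000-cell landscape with a
strong-signal virtual species, the full 8 × 10 ensemble, and 70 simulations
reduced to 7 — the complete design at a grid size that keeps a full run in
the minutes range on one core. The bundled `demo_config()` additionally
trims repetitions to 3 for interactive use. Oracle equivalences (consensus
arithmetic, classification rules, threshold optimality, interpolation
exactness) are checked on small randomized inputs against independent
naive implementations.

## Worked example

```{r example, eval = FALSE}
library(treeshift)

cfg <- demo_config(outdir = "demo_out", seed = 1)
res <- run_pipeline(cfg)

summary(res$ensembles$boreal)      # held-out AUC per technique
res$thresholds$boreal              # the common suitability threshold
res$summaries$boreal               # Table-style regional vulnerability summary
head(res$overlay)                  # cells at risk for several species
res$uncertainty$boreal             # deviance partition of the projections
```

## Known limitations

* Occurrence cells are treated as independent; no spatial cross-validation
  or autocorrelation correction is offered, so held-out AUC on real,
  spatially structured data would be optimistic.
* The uncertainty partition is a main-effects decomposition; interaction
  structure is not separated from the residual.
* True absences are assumed (no pseudo-absence machinery).
* The synthetic ensemble's anomalies are smooth and trend-like; real
  simulation ensembles carry richer spatial structure, so scenario
  selection on real data should be fed real domain-averaged anomalies.
* Rendering of maps is out of scope; classification tables carry
  coordinates so any mapping stack can consume them.
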