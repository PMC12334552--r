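---
title: "Methods: ensemble habitat modelling and climate-driven Red List reassessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat modelling and climate-driven Red List reassessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sdmrisk implements a complete conservation-assessment pipeline for
range-restricted species under climate change: ensemble habitat-suitability
modelling from presence-only records, habitat-change accounting between a
current and one or more future climate scenarios, IUCN Criterion-B range
metrics, a climate-driven Red List reclassification decision table, and a
protected-area gap analysis. This vignette documents the models, their
assumptions, the tunable parameters, and the design decisions taken where
several defensible choices existed.

## Grid geometry and area accounting

All rasters live on a cell-center-registered WGS84 latitude/longitude grid
(`grid_spec`): row 0 is the northernmost row, indices are 0-based, and
point-to-cell assignment uses half-open intervals — `[west, east)` in
longitude, `(south, north]` in latitude — so every point belongs to exactly
one cell. Cell areas use the exact spherical-zone formula
$A = R^2\,\Delta\lambda\,(\sin\varphi_N - \sin\varphi_S)$ with the IUGG
mean Earth radius $R = 6371.0088$ km, so all km² accounting is area-true on
a latitude/longitude grid (cells shrink toward the poles). A full global
grid sums to $4\pi R^2$ to machine precision, and all per-species area
numbers inherit additivity from this formula.

Raster exchange uses the plain-text ESRI ASCII grid format (`read_asc`,
`write_asc`), which round-trips the full registration; protected-area
masks can also be written as GeoJSON rectangle collections. Inputs are
required to be conformant latitude/longitude grids — the package does not
reproject.

## Collinearity filtering

Bioclim-style predictor sets are strongly collinear. `filter_collinear`
computes pairwise Pearson correlations over complete-case cells, scans
pairs in decreasing $|r|$, and whenever a pair exceeds the threshold
(default $|r| > 0.75$) drops the member ranking lower in a user-supplied
priority order (default: stack order). Complete-case correlation keeps the
matrix symmetric and the result deterministic; the greedy
highest-correlation-first order makes the retained set reproducible and
idempotent (re-filtering a retained set changes nothing). Zero-variance
layers have undefined correlations; these are treated as $|r| = 0$ with a
logged warning rather than an error, so a degenerate layer cannot silently
knock out an informative one.

## The ensemble modelling protocol

For each species the training set consists of the unique occupied cells
(presences) and `n_pa` pseudo-absence cells drawn uniformly without
replacement from the valid cells holding no record (default
`max(1000, 10 × n_presences)`). Five base learners are fitted:

| label  | implementation | key defaults |
|--------|----------------|--------------|
| GLM    | binomial logistic regression, linear terms | — |
| CTA    | classification tree (`rpart`) | `cp = 0.001`, `minbucket = 5` |
| GBM    | gradient-boosted trees (`xgboost`) | 60 rounds, depth 3, eta 0.1 |
| RF     | random forest (`randomForest`) | 200 trees |
| MAXENT | ridge-penalized logistic regression on a linear + quadratic + pairwise-product feature basis | lambda 0.01 |

The MAXENT-style learner is the standard presence/background approximation
of maximum-entropy modelling as a regularized logistic fit on an expanded
feature basis; it keeps the algorithm family without an external binary.

Validation uses `n_reps` (default 20) independent stratified random
70/30 splits. A repeated 70/30 split is the only reading consistent with
stating both a 70/30 division and 20 evaluation folds — a literal 20-fold
partition would contradict the 70/30 fractions. Each replicate is scored on
its held-out 30% with AUC (Mann–Whitney pair formulation, ties counted
half) and the maximized True Skill Statistic
(TSS$(\theta)$ = sensitivity + specificity − 1, scanning all midpoints
between adjacent distinct scores; ties resolved toward the smallest
threshold).

An algorithm passes the performance gates when its *mean* held-out AUC and
TSS across replicates strictly exceed `gate_auc` and `gate_tss` (defaults
0.7 and 0.7). Passing algorithms are refitted on all data and combined into
four ensembles: cellwise mean (EMmean), median (EMmedian), committee
average (EMca — each member binarized at its own TSS-optimal threshold, so
values are multiples of $1/m$), and TSS-weighted mean (EMwmean; weights
proportional to member TSS, normalized to one — TSS rather than AUC because
the binarization step downstream is threshold-based, and configurable in
spirit by editing the member evals). Combiners are scored on the pooled
held-out predictions across replicates, and the best combiner maximizes
AUC + TSS with ties resolved by the precedence EMca > EMwmean > EMmean >
EMmedian. Permutation variable importance is $1 - r$ between predictions on
the original and column-permuted data, averaged over shuffles, floored at
zero and normalized to sum to one.

All stochastic steps take explicit seeds. The pipeline derives per-stage,
per-species sub-seeds from the master seed by a stable string hash, so each
species' results are independent of the order of the species list.

## Binarization and habitat change

A cell is suitable when its ensemble score is at least the cutoff (default
0.6, inclusive). A fixed cutoff is the only fully reproducible reading of a
"natural-breaks score ≥ 0.6" rule: Fisher–Jenks breaks depend on the score
distribution of each map, so the package computes the Jenks classification
(exact dynamic programme over sorted values, smallest-first-break
tie-break; subsampled to 1000 quantiles on large maps) only as a logged
diagnostic — the break nearest the cutoff is attached to every binary map —
while the classification itself uses the fixed cutoff.

Change accounting is cellwise: retained = current ∧ future, lost = current
∧ ¬future, gained = ¬current ∧ future; the identities retained + lost =
current and retained + gained = future hold exactly by construction and are
asserted over random mask pairs in the test suite. Net change is
$100\,(\text{future} - \text{current})/\text{current}$, measured on total
suitable area; a per-species lost fraction (lost/current) is also emitted
for sensitivity analysis but does not drive reclassification. Species with
zero current area are flagged rather than erroring. The species-change
histogram uses the bin closures {−100} (total loss), (−100,−70],
(−70,−50], (−50,−30], (−30,0) for losses and [0,200], (200,400],
(400,∞) for gains; closures are fixed conventions because prose bins like
"70%–100%" are ambiguous at their edges.

## Criterion-B metrics

EOO is the convex-hull area of the unique records, computed on a
cylindrical equal-area projection whose standard parallel is the data
centroid latitude, with the x-origin at 0° longitude and the y-origin at
the equator; the projection is area-preserving, and hull edges are straight
in projected space (the difference from geodesic edges stays below about
1% for extents of a few degrees — verified against an independent geodesic
oracle in the tests). AOO counts occupied 2 km × 2 km squares (× 4 km²)
and locations occupied 10 km squares, both grids anchored at the projection
origin so results are bit-reproducible. Fewer than three non-collinear
points give EOO 0, and when a degenerate hull makes EOO < AOO, EOO is
replaced by AOO before thresholding.

The preliminary categorizer applies geographic-range thresholds with
location counts as the operative proxy for the subcriteria: CR when
(EOO < 100 or AOO < 10) with exactly 1 location; EN when (EOO < 5000 or
AOO < 500) with ≤ 5 locations; VU when (EOO < 20000 or AOO < 2000) with
≤ 10 locations; NT within 20% above any VU bound (EOO < 24000 or
AOO < 2400, ≤ 12 locations); else LC. The NT buffer is an explicit
convention — continuing-decline and severe-fragmentation subcriteria are
not modelled. Species without a published category get this preliminary
category combined with an optional user-supplied prior by maximum risk
(`combine_max_risk` — commutative, associative, idempotent, with NE as the
identity), mirroring the practice of adopting the higher risk of two
assessment routes.

## The reclassification decision table

Projected range change maps a ranked start category to an end category.
Loss side ($L$ = percent lost): any species whose projected future range is
exactly zero becomes EX (extinct in the wild); CR with $L > 90$ becomes EX;
EN: $L > 90$ → CR, otherwise EN; VU: $L > 90$ → CR, $70 < L \le 90$ → EN,
$50 < L \le 70$ → NT; NT: $L > 90$ → CR, $70 < L \le 90$ → EN,
$50 < L \le 70$ → VU; LC: $L > 90$ → EN, $70 < L \le 90$ → VU,
$50 < L \le 70$ → NT. Expansion side ($G$ = percent gained): CR:
$100 \le G \le 150$ → EN, $G > 150$ → VU; EN: → VU / NT; VU: → NT / LC;
NT: $G > 100$ → LC. All other cases retain the start category, and exactly
one identified rule fires per call.

Interval closures are strict on "exceeds" ($L > 90$) and inclusive on band
tops ($70 < L \le 90$); the expansion band 100%–150% is closed at both
ends; and EX requires literal total loss (future area exactly zero), never
a loss rounding to 100%. Two properties deserve emphasis. First, the table
is deliberately *not* monotone in risk: a VU species losing 50–70% of its
range is down-listed to NT while an NT species with the same loss is
up-listed to VU — the table is encoded exactly as designed and the test
suite asserts this printed behaviour rather than monotonicity. Second, at
exactly 50% loss the $L > 50$ condition does not fire, so a VU species at
the boundary retains VU even though the change histogram's (−70,−50] bin
contains it; boundary species are therefore counted differently by the
histogram and the rule engine, which is intentional.

The threatened count is |{VU, EN, CR}| plus, by default, |{EX}| —
species going extinct in the wild remain conservation-relevant and
genus-level threat totals are typically quoted that way; setting
`count_ex_as_threatened = FALSE` gives the strict IUCN definition.

The package ships a synthetic 20-species worked example for the genus
*Pachypodium* (`pachypodium_example()`, file
`pachypodium_changes_synthetic.csv`): published categories for ten species,
rule-based fills (7 VU, 3 NT) for the ten unevaluated ones, and
internally consistent range-change values under an intermediate and a high
emission scenario — three species losing their entire range, narrow-ranged
endemics contracting, coastal species expanding. The areas and percentages
are constructed stand-ins, not measurements; they exercise every branch of
the decision table and give stable genus-level counts (13 and 14 threatened
species, 3 extinct in the wild) that the acceptance script recomputes.

## Protected-area gap analysis

`overlay_pa` intersects a binary habitat map with a protected-area mask:
inside = area(habitat ∧ PA), outside = area(habitat ∧ ¬PA), and
inside + outside equals the habitat area exactly. Genus-level trends sum
*per-species* protected habitat (species overlap is intentionally counted
once per species, matching per-species accounting); a union-based
conservation-gap mask (suitable for ≥ 1 species but unprotected) is
available separately via `conservation_gap_mask`. Polygon PA inputs are
expected rasterized with center-of-cell inclusion.

## The virtual-species simulator

Synthetic landscapes are independent Gaussian white-noise fields smoothed
by a separable moving-average window (radius = the autocorrelation range in
cells, edge-normalized) and standardized to zero mean, unit variance.
Virtual species have Gaussian (bell-shaped) responses per layer — the
product across layers mimics niche intersection — rescaled so the best cell
has suitability 1. Presences are drawn with probability proportional to
suitability, with replacement, and jittered uniformly within the cell, so
deduplication and cell assignment have realistic work to do. Future
scenarios are additive layer shifts; blocky protected-area masks are unions
of random rectangles trimmed to within ±2 percentage points of a coverage
target. All generators are pure functions of (spec, seed).

What the simulator does *not* emulate: realistic geography and coastline
masks, sampling bias beyond uniform jitter, dispersal limitation,
interactions between layers, and general-circulation-model spatial
structure in the future deltas. Passing tests on these landscapes show the
pipeline machinery is correct and can recover a known niche; they do not
certify performance on real occurrence data with spatial sampling bias.

## Validation design: parameter recovery

`parameter_recovery_study()` runs the full protocol on a 100 × 100 grid
with two uncorrelated layers, a Gaussian species (breadth 0.7 in
standardized layer units) centred on the current layer means, 300
presences, 1000 pseudo-absences and 20 splits, then measures recovery of
the known truth: the Pearson correlation between ensemble and true
suitability, and the AUC of the ensemble against the *true* binary habitat
(truth ≥ 0.6) at cells held out of training.

Two aspects of this design need explaining. First, recovery is judged
against the truth, not against the sample labels: with a broad niche
(breadth 0.7) the uniform background contains genuinely suitable cells, so
the sample-label AUC of even a perfect model has a closed-form ceiling —
scoring cells by true suitability gives AUC $(1+a)/(2+a) \approx 0.75$ and
maximum TSS $\approx 0.39$ for $a = 1/\sigma^2 \approx 2$ — which measures
the prevalence structure of the design, not model quality (the study
reports this sample AUC alongside, and it sits at that ceiling). Second,
for the same reason no base learner can clear default 0.7/0.7 gates on
such data, so the recovery study builds its ensemble from all five
learners with gating disabled; gate behaviour is validated separately
(label-shuffled models never pass in 50 trials). The demonstration pipeline
in `default_config()` instead uses very narrow-niche species (breadth 0.12),
which behave like the narrow-ranged endemics this kind of analysis targets
and do clear the default gates.

The study sizes (100 × 100 cells, 10 seeds, medians reported) keep the
whole validation reproducible in a couple of minutes while leaving
comfortable margins over the pass thresholds (median truth-AUC ≥ 0.9,
median truth-correlation ≥ 0.8, and a strictly negative net range change
after shifting the dominant layer by +1.5 sd against a species centred on
the current mean).

## Numerical choices and degenerate inputs

* Fisher–Jenks uses an exact $O(kn^2)$ dynamic programme on prefix sums;
  among cost-ties it returns the partition with the smallest first break
  (then second, and so on), matching exhaustive enumeration.
* `max_tss` resolves floating-point ties (mathematically equal TSS reached
  through different count fractions) with a $10^{-12}$ tolerance toward the
  smallest threshold.
* Single-class training sets, empty ensembles, all-nodata maps, zero
  current areas, empty habitats and unresolvable NE categories all fail
  fast with named errors or flagged `NA`s — never silent zeros.
* Constant-feature training data yields a constant-score model rather than
  a fit error, so degenerate simulated species do not abort a batch run.
* RNG state is always restored after seeded sections (`with_seed`), so
  calling package generators never perturbs the caller's random stream.

## Limitations

The reclassification operates on Criterion A-style range-loss proxies and
geographic-range metrics only; population sizes, generation length and
regional adjustments are out of scope. EOO/AOO use one fixed equal-area
projection convention — other tools anchor their occupancy grids
differently and can differ by one cell row at boundaries. The PA analysis
does not filter protected areas by governance category or effectiveness.
The ensemble never extrapolates beyond the score range [0, 1], but
projections into environments far outside the training range inherit the
usual risks of correlative models.
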