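---
title: "Full-annual-cycle spatial prioritization: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Full-annual-cycle spatial prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flywayplan)
```

`flywayplan` implements a pipeline for prioritizing land conservation across
the full annual cycle of migratory species. This vignette is the package's
own account of the science inside it: the models and their assumptions, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open.

## The planning problem

The core object is the *minimum set cover* reserve-selection problem. Given
a grid of planning units (square cells, by default 8.4 km on a side), a cost
per unit, and a collection of *conservation features* — abundance layers
with representation targets — we solve the integer linear program

$$\min_x \; c^\top x \quad \text{subject to} \quad A x \ge b,\; x \in \{0,1\}^n,$$

where $x_j$ says whether planning unit $j$ is selected, $c_j$ is its cost,
$A_{ij} = r_{ij}$ is the representation level (relative abundance) of
feature $i$ in unit $j$, and $b_i$ is feature $i$'s target — by default 30%
of its total abundance. The 30% default is an illustrative, configurable
target intermediate between common policy targets; nothing in the machinery
depends on it.

Features are constructed along three binary axes, giving eight planning
scenarios:

* **weekly vs yearly.** Weekly planning solves one problem per week (each
  species contributes one feature) and sums the 52 solutions, so each cell
  ends up selected 0–52 times. Yearly planning puts every species-week into
  a single problem (117 species × 52 weeks = 6084 features at full scale)
  and returns one binary map. Yearly solutions can reuse a cell across
  weeks, so their total area is never more than the summed weekly areas —
  a nesting property the test suite checks, along with the full chain
  *yearly optimum ≤ cost of the union of weekly optima ≤ sum of weekly
  optima* and *each weekly optimum ≤ yearly optimum*.
* **single population vs spatial clustering.** Clustered scenarios split
  each species-week into $k$ regional abundance clusters (default 5) and
  give every cluster its own 30% target, stratifying protection across the
  range. Because the cluster targets jointly imply the range-wide target,
  the clustered optimum can never be cheaper than the single-population
  optimum (also tested).
* **shared-use vs intact habitat.** Shared-use planning costs every unit 1
  (the objective is then simply area); intact-habitat planning costs each
  unit by a human-footprint-style index in [0, 50], steering solutions away
  from human-dominated land. Costs never enter the feature targets, so the
  cost axis is orthogonal to the other two.

### Solving, exactly

`solve_exact()` hands the sparse problem to the HiGHS branch-and-bound
solver through SciPy's `milp` interface (a small bundled Python helper;
batched so the 52 weekly solves share one solver start-up). The default
`gap_tolerance = 0` proves optimality; a positive relative gap is available
for large runs. `solve_bruteforce()` is a fully independent exhaustive
oracle for instances of at most 20 units — it enumerates all subsets and
breaks cost ties lexicographically — and the test suite requires exact
objective agreement between the two on dozens of random instances.
`verify_solution()` recomputes attainment $Ax$, shortfalls and the
objective without consulting the solver, and every scenario run reports it.

Numerical choices: zero-cost units under footprint costs are floored at
1e-6 so "free" cells cannot proliferate invisibly; features with zero total
abundance are dropped (their constraints are vacuous); cells whose
estimated abundance is missing (insufficient ensemble support, below)
contribute nothing to features or totals, because a rendered estimate is
the only quantity a planner has.

## Estimating weekly abundance from checklists

`fit_stem()`/`predict_abundance()` implement an ensemble of block-local,
two-step zero-inflated models in the spatiotemporal-exploratory-model
tradition. The study extent × year is partitioned into spatiotemporal
blocks; the ensemble is a Monte-Carlo sample of 100 randomly offset
partitions. Blocks are 10° × 10° × 30 continuous days north of 12°
latitude and 20° × 20° × 30 days south of it (coarser where observation
density is lower). Day windows wrap around the year end; since 366 is not
divisible by 30, one window per partition absorbs the six leftover days.

Within each block holding at least 50 checklists with at least 10
detections of the species, a two-step base model is fitted: an *occupancy*
step predicting detection, and an *abundance* step predicting the count
conditional on detection. Blocks failing the rule are removed from the
ensemble. The prediction for a week × cell is the average of
$\hat p \times \hat\lambda$ over all base models whose block contains the
cell centre and the mid-week day, evaluated at a standardized search (one
observer, 7:00 start, 1 h, 1 km); estimates supported by fewer than 50 base
models are reported missing rather than extrapolated. A uniformly random
10% of checklists is withheld before fitting and used only for reporting
validation statistics (`validate_stem()`), never for early stopping.

Three base-learner pairs are available. The literature-standard learner is
boosted regression trees (`learner = "gbm"`, via xgboost) with bag fraction
0.80, shrinkage 0.05, 1000 trees, and depths 5 (occupancy) / 10
(abundance). The default is a fast, deterministic GLM pair — logistic
occupancy and Poisson abundance — over predictors in three classes:
spatial (a quadratic surface in latitude/longitude, a smooth synthetic
elevation covariate, and optionally the landscape metrics below, plus
position × day interactions that let the local mean drift within a 30-day
window), temporal (day of year, year, start time) and effort (log duration,
log(1 + distance), party size). The GLM is not an arbitrary convenience:
the synthetic truth is a Gaussian kernel, whose log-mean is exactly
quadratic in position, so the GLM base learner can represent the target
surface while remaining orders of magnitude faster than boosting — the
recovery experiments below run with it. A third option (`learner = "tree"`,
rpart) is deterministic and piecewise-constant, useful for checking that
block predictions reproduce step-function truths. One guard applies to all
learners: a base model's conditional-abundance prediction is capped at the
largest count observed in its block, because a local model asked to
extrapolate (e.g. a Poisson log-link leaving its block's support) can
otherwise return astronomically large means that a 100-member average
cannot dilute.

### Landscape covariates

`compute_landscape_metrics()` summarises a categorical land cover inside a
2.8 × 2.8 km neighborhood around each location: per class, PLAND (percent
of the neighborhood; sums to 100 across classes), LPI (largest 4-connected
patch, percent), PD (patches per km²) and ED (edge km per km², counting
sides facing another class or the window boundary). Windows at the raster
edge are clipped rather than discarded. These metrics are computed in plain
R over small windows; joining them as predictors is supported but off by
default in the recovery experiments, where the quadratic position surface
already spans the truth and computing four metrics × classes over 20,000
neighborhoods would dominate runtime without changing the conclusions.

## Regional abundance clustering

`cluster_weekly()` delineates each species-week surface into $k$ clusters
of occupied cells (estimated-missing and zero cells excluded). The
dissimilarity between cells min–max scales latitude, longitude and
abundance to [0, 1], multiplies the abundance axis by 1/3, and takes
Euclidean distance — so clusters are driven primarily by geography, with
abundance as a weak third axis. Min–max scaling is a deliberate choice
where several standardizations would be defensible: it makes the 1/3
weight directly interpretable as a fraction of the geographic range, but it
is a divergence risk against any analysis that standardized differently,
and whether abundance should first be log-transformed is equally open (we
do not transform).

Clustering uses CLARA, the subsampling extension of k-medoids: PAM
(BUILD + SWAP) on each of 5 subsamples of size `min(n, 40 + 2k)`, all
points assigned to the nearest candidate medoid (ties to the lowest medoid
index), best medoid set kept. Since SWAP only guarantees a local optimum,
PAM here adds 10 seeded random restarts and keeps the best local optimum —
at test sizes this reliably reaches the global optimum found by exhaustive
medoid enumeration. Clusters are re-drawn independently every week; no
cross-week cluster identity is implied. "Equal abundance" among clusters is
a reporting concept, not a constraint: per-cluster abundance shares are
always reported, and an optional greedy boundary-cell rebalancing pass
(off by default) can nudge shares toward $1/k$. A week with fewer occupied
cells than $k$ falls back to a single cluster with a warning.

## The synthetic landscape

Because the real inputs (a continental checklist database, a global
human-footprint raster, a 300 m land-cover map) are not shippable, the
`synthetic_landscape` module generates inputs with the statistical
structure the analysis assumes. Its defaults are the study conditions of
the package's tests and acceptance runs:

* **Grid.** Locally flat, 8.4 km square cells, 0-based row-major ids,
  half-open extents; degrees are km / 111.32. Latitude only matters for the
  ensemble block-size rule.
* **Species.** Weekly abundance is an isotropic Gaussian kernel (sd
  `spread_km`) centred on a 52-week migration route interpolating between
  stationary non-breeding (weeks 49–8) and breeding (weeks 24–35) ranges,
  roughened by seeded lognormal noise (sd 0.15 on the log scale) and
  truncated at 1e-4 of the weekly maximum so each species has a finite
  weekly range; the surface is then rescaled so every weekly total equals
  `total_abundance` exactly (the conservation invariant downstream checks
  rely on). The community default kernel scale is 1.2 cell widths, making
  a species' weekly range roughly 10–20% of a 20 × 20 study grid — the
  desk-scale analogue of a hemispheric system in which any one species'
  weekly range is small relative to the planning domain. (Ranges spanning
  half the grid are both unrealistic in miniature and produce massively
  degenerate cover problems.)
* **Checklists.** Search events are placed uniformly (an effort-density
  surface can be supplied; the spatial distribution of real observer effort
  is deliberately not modelled), with lognormal duration and distance,
  1 + Poisson party sizes, uniform day of year and year. Counts follow a
  zero-inflated Poisson: occupancy is logistic in log abundance, detection
  is `1 - (1 - q)^party_size` (party size affects detection only), and the
  count mean is `detection_scale × abundance × duration × sqrt(1 +
  distance)` — monotone in effort and closed-form, so Monte-Carlo means
  can be checked analytically with `expected_count()`.
* **Costs.** Uniform mode is exactly 1 everywhere; footprint mode is a
  Gaussian-smoothed random field clipped to [0, 50].
* **Land cover.** Fine cells (planning cell / `fine_factor`; factor 28
  turns 8.4 km into 0.3 km pixels) drawn iid from configured class
  proportions. There is deliberately no spatial autocorrelation in the
  default: iid sampling is what makes the class-histogram checks exact, and
  none of the landscape-metric algebra depends on autocorrelation.

What passing tests on these data do **not** show about real data: the
generator has no spatially clumped observer effort, no interannual trend,
no observer heterogeneity beyond party size, no detection dependence on
habitat, perfectly nested land-cover grids, and smooth unimodal species
ranges. Estimator recovery here demonstrates correctness of the ensemble
machinery, not field performance.

## Study sizes used by tests and the acceptance script

The packaged experiments run at deliberately modest sizes: solver-oracle
sweeps on 50 random instances of ≤ 15 units and ≤ 6 features; scenario
structure on a 20 × 20 grid with 5 species, 8 weeks and k = 3; estimator
recovery on a 12 × 12 grid, 52 weeks, 100 partitions, 20,000 vs 2,000
checklists with the GLM learner (Spearman rank correlation against truth
≥ 0.8 over supported cells, and mean absolute error decreasing with more
data). These sizes are the package's choices for a reproducible desk-scale
study; the machinery itself is size-agnostic, and headline percentages
computed at this scale are not comparable to any full-scale analysis.

## Known limitations

* Weekly problems are fully independent — no locked-in-area constraint
  links consecutive weeks.
* The agreement map binarizes weekly scenarios at "selected in ≥ 1 week"
  by default; the threshold is exposed because other conventions are
  defensible.
* Both summed and union areas are always reported for weekly scenarios,
  since "total area across weeks" double-counts cells reused in several
  weeks.
* The availability mask for land-cover accounting defaults to "≥ 1 species
  present in any week" with the species threshold configurable.
* CLARA reports, but does not enforce, equal abundance shares.
* No geographic projections, ocean masking, or real-data ingestion: grids
  are locally flat and rasters are in-memory matrices exported as CSV.
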