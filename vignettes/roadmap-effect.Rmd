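---
title: "Quantifying the road-map effect in occurrence records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the road-map effect in occurrence records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
```

```{r setup, message = FALSE}
library(roadbias)
library(dplyr)
```

## The problem

Biological collections are not random samples of the landscape. Collectors
travel by road, so herbarium specimens and other occurrence records tend to
accumulate near road networks — the *road-map effect*. Any downstream use of
such records (species distribution models, diversity mapping, gap analysis)
inherits this accessibility bias. `roadbias` quantifies the effect with three
complementary measures, each comparing the observed record pattern against an
explicit null in which records are uniform over the study region, and then
models the *intensity* of the effect as a function of environmental and
socio-economic covariates with a spatially explicit random forest.

All geometry lives in a projected equal-area plane with km units. Buffer
fractions and densities are ratios of areas, which degree-based coordinates
would distort, so longitude/latitude inputs are reprojected (Albers
equal-area conic) once, at load time.

## The three measures

**1. Nearest-road distance null model.** For $n$ observed records the mean
nearest-road distance $\bar d_{obs}$ is compared with the means
$\bar d^{(1)}, \dots, \bar d^{(R)}$ of $R$ patterns of $n$ uniform random
points (default $R = 1000$). The effect is significant when
$\bar d_{obs}$ falls below the 5th percentile of the replicate means. Two
summary statistics accompany the test: the ratio
$\bar d_{obs} / \mathrm{mean}(\bar d^{(r)})$, which approaches 0 as the
observed pattern deviates from randomness, and the shape parameter $k$ of a
gamma distribution fitted to the observed distances by maximum likelihood
(scale $\theta$ unconstrained). Smaller $k$ means the record count decays
faster with distance from the road: a stronger roadside bias.

**2. Buffer clustering ($P_{clustering}$).** With a dissolved buffer of
radius $d$ (5 or 10 km — distances walkable in one or two hours) around all
roads, a uniform record falls inside the buffer with probability $p_d$, the
buffered fraction of the region's area. Out of $N$ records, $n_d$ observed
inside the buffer are scored against $X \sim \mathrm{Binomial}(N, p_d)$:

$$P_{clustering} = \begin{cases}
P(X \le n_d - 1) & n_d > N p_d \\
0.50 & n_d = N p_d \\
P(X \le n_d) & n_d < N p_d
\end{cases}$$

so values above 0.95 indicate significant clustering inside buffers
(right-tailed $p < 0.05$) and values below 0.05 significant avoidance. The
statistic is computed nationally and county by county; the county $p_d$ is
the buffered share of that county's own area, with the buffer built once
around all roads and clipped per county.

**3. Road density null model.** The mean road density (km of road per km²)
in discs of radius 5–60 km around the observed records, against the same
uniform null; significant when the observed mean exceeds the null's 95th
percentile.

Monte-Carlo p-values use the add-one estimator $(1 + r)/(1 + R)$, which can
never report an impossible zero; percentiles are linear interpolation on the
sorted replicate means.

## Covariate analysis

The intensity measures are regressed on covariates with a random forest
(out-of-bag $R^2$ as variance explained). Because forests have no
likelihood, stepwise backward selection uses a pseudo-AIC,
$n \ln(\mathrm{MSE}_{oob}) + 2(p + 1)$: monotone in out-of-bag fit,
penalizing predictor count, and reproducible. This is a deliberate,
documented surface for the "AIC" of a forest, which has no standard
definition.

Residual spatial autocorrelation would inflate type-I error, so the pipeline
builds PCNM spatial filters: pairwise distances are truncated (entries above
a threshold $t$ replaced by $4t$), the matrix is double-centered as
$-\tfrac12 H D^2 H$ and eigen-decomposed, and the positive-eigenvalue
eigenvectors — broadest spatial scales first — serve as candidate
covariates. Filters are added greedily (largest marginal gain in out-of-bag
$R^2$ first) until global Moran's I of the out-of-bag residuals is
insignificant; if the candidate pool is exhausted first, the result carries
an `unresolved` flag rather than a silent pass. Relative importance is the
permutation importance (increase in out-of-bag MSE), negatives floored at
zero, normalized to sum to 100 across predictors and filters; Pearson
correlations give the sign of each relationship.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `reps` | 1000 (tests use 200) | — | Monte-Carlo replicates; 200 gives a p-value floor of 1/201 while keeping desk runs fast |
| `d` | 5 or 10 | km | buffer radii walkable in 1–2 h |
| `radius` | 5–60 | km | road-density disc radii |
| `truncation` | 300 (continental); MST rule otherwise | km | PCNM threshold; `NULL` uses the longest minimum-spanning-tree edge, the classical PCNM default, which suits sub-continental extents |
| `moran_radius` | 10 | km | residual Moran neighbour band: the first correlogram class at the 100 km test extent |
| `alpha` | 0.05 | — | residual-autocorrelation significance |
| `ntree` | 500 | — | forest size; OOB quantities stabilize well before this at $n \approx 10^3$ |
| `max_filter_candidates` | 10 | — | greedy pool; broad-scale filters do the work, and a bounded pool keeps the loop $O(10)$ fits per step |

The Moran weights are binary distance-band, row-standardized — the simplest
scheme consistent with a correlogram's first class; the analytic null
expectation is $-1/(n-1)$ with normal-approximation p-values.

## The synthetic generator

Real specimen databases and historical road maps are rarely deposited in
machine-readable form, so every analysis stage is validated against
generated data with known truth:

* **Region**: a rectangle partitioned into an exact grid of "counties".
* **Roads**: random chords between perimeter-uniform boundary points;
  `densify = k` extends the same seed stream so a sparser period's network
  is a strict subset of a denser one, emulating decade-to-decade growth.
* **Occurrences**: three modes. *Offset* places each record at a
  perpendicular gamma$(k, \theta)$ offset from a length-weighted random
  point on a road; draws landing outside the region are re-drawn, not
  clipped, so the offset law stays exactly gamma, and for a single straight
  road the nearest-road distance *equals* the drawn offset — the estimator
  can be tested in isolation from null-geometry confounding. *Thinning*
  accepts uniform proposals with probability $e^{-d/\lambda}$, a more
  realistic multi-road decay. *Uniform* is the null.
* **Covariates**: random-cosine-basis surfaces (64 terms) approximating
  unit-variance Gaussian processes with a squared-exponential length scale
  of half the stated range — $O(nm)$ cost, reproducible, smoothness
  controlled — plus a linear response with known effects, a spatially
  correlated noise surface, and white noise.

The standard scenario used across the tests is a 100 × 100 km region with a
4 × 4 county grid, 12 chords, 1000 records placed by offsets with
$k = 0.40$ and mean 3.6 km (a strong roadside bias at the severe end of
what herbarium data show), and four covariates with effects
$(1.0, 0.5, 0, 0)$ and 25 km range, plus a spatially correlated noise
surface (sd 0.5, 50 km range) and white noise (sd 0.5). The covariate range
is deliberately kept at a quarter of the extent: independent smooth fields
whose range approaches the region size are strongly mutually correlated by
chance, and "known independent effects" would then not be recoverable by
any method. Problem sizes in the test-suite (e.g. 200 replicates, 100 calibration
trials, 20 recovery seeds, `ntree = 500`) are chosen so the whole suite
runs on a laptop in well under half an hour.

What passing these tests does *not* show: the generator has no road-graph
topology (intersections, road classes), no species abundance structure, no
temporal collector behaviour, and its counties are exact rectangles.
Conclusions about estimator calibration transfer to real data only insofar
as real sampling resembles the offset/thinning mechanisms.

```{r scenario}
sim <- simulate_scenario(seed = 1)
sim$roads
dt <- roadmap_distance_test(sim$occurrences, sim$region, sim$roads,
                            reps = 200, seed = 2)
dt
```

```{r clustering}
national_clustering(sim$occurrences, sim$roads, sim$region, d = 5)
cty <- county_clustering(sim$occurrences, sim$roads, sim$region, d = 5)
plot_clustering_map(cty, sim$region, sim$roads)
```

```{r model}
cdat <- sim$covariates$data
mdl <- roadbias_rf(select(cdat, -x, -y), "response", select(cdat, x, y),
                   ntree = 500, seed = 3)
glance(mdl)
tidy(mdl)
```

## Numerical choices

* **Buffer areas** are censused on a deterministic grid with cell size
  $d/128$ (capped at $8 \times 10^6$ cells), with irrational grid offsets
  so cell-centre rows cannot align systematically with axis-parallel buffer
  edges. The single-segment closed form $2Ld + \pi d^2$ is matched to a few
  parts in $10^5$; 0.5% is the documented tolerance. Buffer *membership*
  of records is exact (distance predicate), never discretized, so the
  buffer/distance duality holds identically.
* **Area fractions** census the region and the buffer∩region on the same
  grid, so the ratio is self-normalizing.
* **Segment-in-disc clipping** (road density numerator) is closed form;
  disc∩region areas short-circuit to $\pi r^2$ for interior discs and use
  exact interval arithmetic in $y$ with a midpoint rule in $x$ otherwise.
* **Gamma MLE**: records lying exactly on roads give zero distances, which
  unbound the gamma likelihood for $k < 1$; zeros are replaced by half the
  smallest positive distance, preserving sample size. The fit runs on
  mean-scaled data (shape is scale-invariant) with a direct likelihood
  `optim` fallback behind `MASS::fitdistr`.
* **$P_{clustering}$ ties**: the 0.50 branch applies only when $N p_d$ is
  an integer exactly equal to $n_d$ (tolerance $10^{-9}$ relative); for
  non-integer expectations one of the two strict branches always applies,
  keeping the statistic total and single-valued. Counties with degenerate
  $p_d \in \{0, 1\}$ are reported and flagged untestable, not dropped.
* **PCNM sign**: eigenvectors are unit-norm with the first nonzero loading
  made positive, so results are deterministic up to machine precision.
* **Determinism**: every stochastic function takes an optional `seed`
  applied locally (the caller's RNG state is untouched); the forest engine
  is single-threaded and seeded, and predictor columns are sorted before
  fitting so column order cannot change a fit.

## Known limitations

* Geometry is planar: geodesic distances and along-road network distances
  are out of scope, as are raster covariates (covariates arrive as a
  per-record table).
* Uniform nulls treat the full region polygon as the support; excluding
  water bodies or uninhabitable terrain would need a masked region polygon.
* The pseudo-AIC is a pragmatic ranking device, not an information
  criterion with likelihood semantics.
* County responses analysed at record coordinates; if a per-county response
  is modelled, use county centroids as coordinates for the spatial filters.
* Record-level quality control can enforce duplicate and completeness
  rules, but georeferencing *precision* cannot be validated without a
  gazetteer; a `precise` flag is honoured when present.
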