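# roadbias

Quantifying the **road-map effect** — the dependence of the geography of
biological collections on road networks — in species occurrence data.

Occurrence records from herbaria and survey databases cluster near roads
because that is where collectors can go. `roadbias` is for biodiversity
informaticians and spatial ecologists who need to measure that bias, track
its change across decades of road-network growth, and relate its intensity
to environmental and socio-economic drivers, before trusting occurrence
data for distribution modelling or survey planning.

## What it computes

Three measures compare the observed records against a null in which the same
number of points is uniform over the study region:

1. **Nearest-road distance null model.** The observed mean nearest-road
   distance $\bar d_{obs}$ against 1000 Monte-Carlo uniform patterns; a
   significant road-map effect is declared when $\bar d_{obs}$ falls below
   the 5th percentile of the replicate means. Reported alongside: the ratio
   $\bar d_{obs}/\mathrm{mean}(\bar d_{null})$ (toward 0 = stronger bias)
   and the maximum-likelihood shape $k$ of a gamma fit to the observed
   distances (smaller $k$ = record numbers decay faster with distance from
   roads).
2. **Buffer clustering.** With $N$ records, $n_d$ of them within distance
   $d$ of a road, and $p_d$ the buffered fraction of the region's area, the
   binomial statistic

   $$P_{clustering} = \begin{cases} P(X \le n_d - 1) & n_d > N p_d\\
   0.50 & n_d = N p_d\\ P(X \le n_d) & n_d < N p_d \end{cases}
   \qquad X \sim \mathrm{Bin}(N, p_d)$$

   lies strictly in $(0,1)$: above 0.95 = significant clustering inside the
   road buffers, below 0.05 = significant avoidance. Computed for the whole
   region and per county (buffer built once, clipped per county).
3. **Road density null model.** Mean road density (km/km²) in 5–60 km discs
   around the records, significant when above the null's 95th percentile.

A spatially explicit random forest then models each intensity measure from
covariates: stepwise backward selection by a pseudo-AIC
$n\ln(\mathrm{MSE}_{oob}) + 2(p+1)$, PCNM spatial filters (eigenvectors of
the double-centered, truncated distance matrix) added greedily until global
Moran's I of the out-of-bag residuals is insignificant, permutation
importance normalized to 100%, and Pearson correlations for effect signs.

Because real specimen databases and historical road maps are rarely
deposited, the package ships a synthetic-data generator (regions with county
grids, growing random road networks, occurrence patterns with gamma-offset
or exponential-thinning roadside bias, covariate surfaces with known
effects) so every stage is testable end to end with known ground truth.

## Worked example

```r
library(roadbias)
library(dplyr)

sim <- simulate_scenario(seed = 1)   # 100x100 km, 12 roads, 1000 biased records
roadmap_distance_test(sim$occurrences, sim$region, sim$roads,
                      reps = 200, seed = 2)
#> Road-map effect: nearest-road distance null-model test
#>   observed mean distance: 1.657 km (n = 1000)
#>   null mean: 5.324 km, 5th percentile: 5.056 km (200 reps)
#>   ratio observed/null: 0.311, p = 0.004975  [significant road-map effect]
#>   gamma decay index: k = 0.448, theta = 3.699 km
```

The records sit 1.66 km from a road on average where uniform sampling would
put them at 5.3 km — a ratio of 0.31, below every one of the 200 null
replicates (`p = 1/201`), with a gamma shape of 0.45 (generated: 0.40, a
strong roadside decay).

```r
national_clustering(sim$occurrences, sim$roads, sim$region, d = 5)
#> # A tibble: 1 × 8
#>   scale    unit      N   n_d   p_d     d p_clustering category
#>   <chr>    <chr> <int> <int> <dbl> <dbl>        <dbl> <chr>
#> 1 national all    1000   913 0.618     5            1 significant clustering
```

62% of the region lies within 5 km of a road, but 91% of records do:
`P_clustering` rounds to 1 — far beyond the 0.95 significance line.

```r
cdat <- sim$covariates$data
mdl <- roadbias_rf(select(cdat, -x, -y), "response",
                   select(cdat, x, y), ntree = 500, seed = 3)
tidy(mdl)
#> # A tibble: 5 × 3
#>   term              pearson_r importance_pct
#>   <chr>                 <dbl>          <dbl>
#> 1 cov1                  0.857          62.3
#> 2 cov2                  0.345          11.0
#> 3 cov3                 -0.314           7.95
#> 4 cov4                 -0.228           6.27
#> 5 1 spatial filters    NA              12.4
glance(mdl)$r2
#> [1] 0.869
```

The forest explains 87% of the variance; the two covariates with true
effects (1.0 and 0.5) rank first and second with positive correlations, and
one PCNM filter suffices to leave the residuals without detectable spatial
autocorrelation (Moran's I p = 0.73).

`autoplot()` methods draw the null-distribution histograms and the
importance chart; `plot_clustering_map()` draws the five-category county
choropleth. `run_pipeline()` chains simulation → QC → all three tests →
model and writes CSV/GeoJSON/JSON outputs reproducibly from one seed.

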