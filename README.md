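# flyway

Delineation of migration corridors and detection of their long-term changes
from two complementary location sources: decades of verified opportunistic
sightings and recent GPS telemetry. The package was built around the
whooping crane (*Grus americana*) Aransas–Wood Buffalo flyway — a ~3,900-km
south–north corridor across the Great Plains — but every stage is generic
tabular-in/tabular-out and works on any comparable two-source location
dataset.

It is aimed at movement ecologists and conservation analysts who need (a) a
defensible corridor polygon with uncertainty bands for planning and
regulatory work, and (b) a quantitative answer to "has the corridor moved or
narrowed?".

## Method

All locations are projected to a North America Equidistant Conic plane
(standard parallels 20°N/60°N, central meridian 96°W, NAD83), so northings
are true ground distance. The flyway is cut into W equal-height latitudinal
**analysis windows** (300 km tall, W = 13 by default; the height can also be
selected from 50–700 km candidates by requiring ≥95% bootstrap containment
and minimizing the fractal dimension index FRAC = 2·ln(0.25·P)/ln(A)).

**Corridor delineation.** Within window *w*, the *p*% core corridor is the
band between symmetric easting percentiles — (25, 75) for the 50% core,
(12.5, 87.5) for 75%, (2.5, 97.5) for 95% — estimated separately from the
screened sightings and the reduced telemetry locations and combined as a
weighted average with weights equal to the per-window sample sizes n₍opp,w₎
and n₍tel,w₎. Edges are joined into a polygon; 1,000 bootstrap resamples of
each dataset give percentile confidence bands.

**Input reduction.** Sightings: only `confirmed` records, excluding Canadian
records dated 25 May–20 Aug (sedentary summering). Telemetry: per-bird
sequential QC (monotone timestamps; displacement rate ≤ 100 km/h; no turn
angles < 5° with both legs > 50 km), flight/ground split at 2.6 m/s
instantaneous velocity, ground fixes chained into stopover sites broken by
\>15 km moves, and one analysis location per stopover centroid plus each
in-flight fix.

**Trend analysis.** A two-stage Bayesian linear model with Gibbs sampling
(2,000 burn-in, 10,000 retained draws): easting (or centerline offset) is
regressed on year with a per-window intercept αᵂ and slope βᵂ (cell means).
Stage 1 fits the sightings under flat priors; each stage-1 posterior
coefficient mean and variance becomes an independent normal prior for stage
2, which fits the telemetry data, and the stage-2 posterior is the
inference. Per-window slopes (km/year, east positive) with 95% credible
intervals quantify corridor shift; the same machinery applied to |offset|
and to the west/east subsets of the centerline offsets quantifies narrowing
and flank-specific movement. A bootstrap comparison of per-window medians
over the overlapping years (2010–2016) screens for systematic bias between
the two sources.

A synthetic-flyway generator (`flyway_scenario()`) with analytically known
quantiles and slopes backs the whole test suite: side-signed half-normal
lateral offsets, eastward drift of the centerline, and contraction
concentrated on the western flank.

## Worked example

Simulate a study-scale flyway, delineate corridors, and fit the trend
models:

```r
library(flyway)

cfg <- flyway_config(
  out_dir = "corridor-run", scenario = flyway_scenario(),
  window_height = 300e3, B = 500, burn = 1000, keep = 5000, seed = 42
)
paths <- run_simulate(cfg)
cfg$sightings <- paths$sightings
cfg$telemetry <- paths$telemetry

del <- run_delineate(cfg)
del$corridors$core_95
#> <flyway_corridor> 95% core: 13 windows, mean width 293 km, area 114.3 Mha

tr <- run_trend(cfg, grid = del$grid)
dplyr::filter(tr$slopes, model == "position")
#> # A tibble: 13 × 6
#>   window slope_mean_km_per_year cl_lo cl_hi excludes_zero model
#>    <int>                  <dbl> <dbl> <dbl> <lgl>         <chr>
#> 1      1                   1.50  1.26  1.73 TRUE          position
#> 2      2                   1.70  1.49  1.94 TRUE          position
#> 3      3                   1.89  1.65  2.12 TRUE          position
#> # …
```

The 95% core corridor averages 293 km wide (SD 50) over the 13 windows and
covers 114 Mha. Every window shows a significant eastward positional trend
of ~1.4–1.9 km/year — the generative truth here is 1.56 km/year (1.2 km/year
centerline drift plus the asymmetry induced by a 0.9 km/year west-flank
contraction), so the fitted rates bracket it. `tr$predictions` converts the
slopes into predicted positions for 1980 and 2014 per window, and
`autoplot()` methods draw the corridor ribbon and the per-window slope
intervals.

Outputs written beside the run: corridor and confidence-band polygons as
GeoJSON, per-window edge tables and slope summaries as CSV, and a JSON run
report with the filter-by-filter attrition counts and the resolved
configuration (every run is reproducible from that file plus the seed).

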