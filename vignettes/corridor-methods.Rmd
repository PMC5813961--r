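---
title: "Corridor delineation and trend models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corridor delineation and trend models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flyway)
```

This vignette documents the statistical model behind `flyway`, the choices
that were genuinely open when the package was designed, and what the
synthetic test bed does and does not establish about real data.

## The estimation problem

A migration corridor is a long, narrow, latitude-spanning region that is
only softly defined by data: decades of opportunistic sightings (verified,
but haphazardly sampled and spatially coarse) and a few years of GPS
telemetry (precise and unbiased, but temporally shallow). The package treats
the corridor as a *per-latitude quantile band*: within equal-height analysis
windows stacked along the projected y-axis, the p% core is the interval
between symmetric easting percentiles. This is deliberately
distribution-free — no kernel bandwidths, no utilization distributions —
and each window borrows no strength from its neighbours, so the corridor
can widen and bend freely with latitude.

### Projection

All geometry happens on a North America Equidistant Conic plane (GRS80
ellipsoid / NAD83; standard parallels 20°N and 60°N, central meridian 96°W,
origin 40°N — the common published parameterization; the exact parallels
are configurable because they are not uniquely determined by convention).
Equidistant conic preserves distance along meridians exactly, which is the
property the analysis leans on: window heights in metres are true
north–south ground distances. The forward and inverse mappings use the
standard meridional-arc series; the tests verify the inverse identity to
1e-6 degrees and meridian distances against an independent geodesic oracle
to 0.5%.

### Windows, edges, polygons

Windows are half-open `[y0 + (w-1)h, y0 + wh)`, lower-inclusive, numbered
south to north, with the grid anchored flush at the minimum northing of the
data (`W = ceiling(span/h)`). Per window and per dataset, west/east edges
are the lower/upper percentiles with linear interpolation between order
statistics (`stats::quantile()` type 7). The definition is configurable
since edges differ at O(1/n) between conventions. The two datasets'
edges are combined as an average weighted by their per-window sample sizes;
a window empty in one dataset takes the other's edge; a window empty in
both is linearly interpolated from its estimated neighbours (terminal empty
windows truncate the corridor instead — extrapolating an edge outward has
no data support).

Polygon vertices sit at window vertical midpoints, with the first and last
windows squared off to the grid's outer boundaries; the window mid-height
is also where reported per-window widths are measured. Containment tests
are boundary-inclusive, so a location exactly on an edge never counts
against the corridor. The fractal dimension index of a polygon with
perimeter P and area A (both in metres) is `2 ln(0.25 P) / ln(A)`: exactly
1 for squares, increasing toward 2 with boundary complexity; it has a known
mild area dependence, which is why it is only ever compared across
candidates built from the same data. Values are reported raw, never
clamped.

### Window-height selection

Candidate heights 50–700 km in 50-km steps are scored on two axes: *data
fit* — the mean over 1,000 bootstrap-replicate corridors of the fraction of
all original locations contained, which must reach 0.95 — and *shape
complexity*, the fractal index of the point-estimate corridor, minimized
among the passers (ties to the smaller height). The containment rule could
also have been read as per-replicate ("95% of replicates contain 95%") or
restricted to one dataset; the averaged form was chosen as the least noisy
and is recorded here because the choice is not forced. Note a real
phenomenon the tests exhibit: when the two sources disagree strongly (the
default nonstationary scenario's telemetry era is much narrower and farther
east than the pooled sighting history), the weighted-average edges can
under-contain the pooled cloud at *every* height, and selection then fails
loudly with per-candidate diagnostics rather than returning a bad height.

## Input screening

Sightings: only `confirmed` classifications, minus Canadian records dated
25 May–20 Aug **inclusive** (the endpoints are kept in the exclusion — the
rule says "between", and including the boundary days is the conservative
reading for a sedentary-period filter). Unparseable dates are logged
rejections, never errors.

Telemetry QC is sequential per bird: (1) timestamps must strictly increase
relative to the last retained fix; (2) a fix implying > 100 km/h from the
last retained fix is dropped — the *later* fix of the pair, with screening
resuming from the last retained one, since the rule cannot identify which
endpoint is wrong and dropping the earlier would discard a fix that already
passed; (3) the apex of any turn < 5° with both legs > 50 km is dropped
iteratively. All inequalities are strict, matching the stated thresholds
(2.6 m/s flight split, 100 km/h, 5°, 50 km, 15 km stopover break). A fix
with a missing velocity is classified *ground*: most fixes are ground
fixes, and the cost of misclassification is asymmetric — a flight fix
called ground joins a stopover centroid, whereas a ground fix called flight
enters the analysis individually. The QC pass is idempotent, and every
dropped record appears exactly once in a reasoned rejection log.

Stopover clustering uses sequential chaining — a new site whenever
consecutive ground fixes are > 15 km apart — rather than a cluster-diameter
rule; the two differ (a chain of 10-km steps spanning 40 km is one site
under chaining), and the tests pin the chaining semantics explicitly.
Migration-period delineation is an input (per-bird date ranges), not an
inference; automatic phenology segmentation is out of scope.

## The two-stage trend model

The response (easting, or signed/absolute centerline offset, metres) is
modelled as `y = α_w + β_w (year − c_w) + ε`, `ε ~ N(0, σ²)`, with one
intercept and one slope per analysis window (cell means, 2W coefficients,
one shared error variance). Gibbs sampling alternates the two conjugate
updates (coefficients | variance: multivariate normal; variance |
coefficients: inverse gamma with a vague IG(0.001, 0.001) prior). Chain
lengths are fixed (2,000 burn-in, 10,000 retained by default) and never
auto-extended: reproducibility from seed beats adaptivity here.

Stage 1 fits the sightings under flat coefficient priors (the coefficient
update then centres on the least-squares solution, which is also the test
oracle). Stage 2 re-fits on telemetry with each coefficient's prior set to
its stage-1 posterior mean and variance as an independent normal. Only
coefficient priors transfer — a normal mean/variance pair cannot describe
the error variance, which gets the same vague prior in both stages.

### Why the year covariate is centered per window

Only *marginal* means and variances cross between stages. If the intercept
is anchored at calendar year 0 = 1942, far from the data's year centroid,
each window's intercept and slope are posterior-correlated at about −0.9,
and discarding that covariance makes the transferred prior claim
substantially more joint information than stage 1 actually has: in a
closed-form check the stage-2 slope SD comes out ~20% too small and
credible-interval coverage drops to ~86%. Centering the year covariate at
each window's stage-1 mean year makes intercept and slope exactly
orthogonal, so the per-parameter transfer preserves the full stage-1
information and calibration is restored (the acceptance suite verifies
~95% coverage and ~5% null false positives). Slopes are invariant under
this reparameterization; the stage-2 design reuses the stage-1 centers
(`trend_design(..., centers = )`), and predictions for reference years
(1980/2014) are mapped back to the calendar frame through the stored
centers. The 1942 origin remains the reporting convention; it is simply not
the internal parameterization.

Other modelling conventions: a window contributes a stage's likelihood only
with ≥ 2 distinct observation years there (otherwise its slope is
unidentifiable and the design would be rank-deficient); a window present
only in stage 2 falls back to a flat prior with a warning; the corridor
centerline is the per-window median easting of the combined data over *all*
years (an offset of exactly zero counts as east — the tie is immaterial but
must be fixed); the west/east flank models use the signed offset restricted
by observed side, so a positive west-flank slope reads "the west flank is
moving toward the median". Per-window credible intervals for the flank
models are conditional on the estimated centerline; its sampling error is
not propagated, so their calibration is assessed on the positional model
(exact analytic truth) while flank recovery is asserted on the average rate
and the direction of detections. The bootstrap median comparison over the
overlapping years flags windows with < 30 sightings as unevaluated rather
than dropping them.

## The synthetic flyway

`flyway_scenario()` generates both raw input tables with known ground
truth. Lateral structure is a side-signed half-normal: a location falls
west or east of the centerline with probability ½ and at a distance
`|N(0, σ_side(w, t))|` km. This family was chosen because it makes flank-specific
contraction expressible and *analytically tractable*: the
combined 2.5th/97.5th percentiles sit exactly at −1.96 σ_west and
+1.96 σ_east, the median sits exactly on the centerline, and the expected
positional year-slope is `drift + √(2/π)/2 (c_west − c_east)` km/year for
scale-contraction rates c. Defaults mirror the study conditions: a
~3,900-km flyway tiled by 13 × 300-km windows, ~5,000 sightings over
1942–2016, 58 birds over 2010–2016 at 4–5 fixes/day, base scales 70–110 km
growing south to north, drift 1.2 km/year, west contraction 0.9 km/year,
stable east flank. Telemetry tracks are generated as stopover ladders
(100–400 km spacing, 1–4 dwell days, ≤ 5-km ground jitter, interpolated
in-flight fixes) whose every fix passes QC by construction at artifact rate
zero; `inject_artifacts()` plants violations of exactly one QC rule each,
with truth labels. Angle artifacts are only planted where the neighbouring
fixes nearly coincide — a < 5° spike with > 50-km legs placed between
distant neighbours would necessarily also trip the speed rule, and the
generator falls back to a speed artifact there rather than plant an
ambiguous case.

What the generator does *not* emulate: spatial reporting bias and rounding
of opportunistic sightings, within-bird autocorrelation beyond the stopover
structure, heteroskedastic observation error, weather- or habitat-driven
route choice, and year-to-year cohort effects. Passing tests therefore
establish that the estimators recover the parameters of this generative
law — not that the law is a complete description of crane data. Two known
consequences are worth naming: the bootstrap resamples individual locations
(as the method prescribes), so on real telemetry its bands understate
within-bird dependence; and the default scenario's strong nonstationarity
makes the two sources genuinely disagree, which the containment diagnostic
reports honestly (see above) — the corridor containment invariant
(0.95 ± 0.01 at n = 20,000) is checked on a single-source corridor, where
the quantile construction makes it a near-tautology and deviations flag
polygon-construction errors.

## Problem sizes and numerical details

The test suite runs study-scale geometry with reduced Monte-Carlo sizes
chosen to keep the full suite at a few minutes: parameter-recovery coverage
uses 200 replicates of 2,000 sightings + 600 telemetry locations with
500/2,000 chains (the sampler's conjugate updates mix essentially
immediately, so short chains cost precision, not correctness); bootstrap
calibration uses 500 replicates at n = 500 with B = 1,000; the null
false-positive check uses 60 replicates. Monte-Carlo standard errors in
sampler-vs-least-squares comparisons come from batch means (30 batches),
and with ~150 simultaneous coefficient comparisons the criterion is that
≥ 98% fall within 3 MCSE and none beyond 6 — a family-wise reading of
"agrees at Monte-Carlo scale". Degenerate inputs are contracts, not
surprises: empty windows yield flagged-missing edges (never zero), an
all-identical-easting dataset yields zero-width bands, self-intersecting
rings and sub-1-m² areas are errors naming the offending geometry, and a
collinear design names its collinear columns.

## Limitations

* The method is purely marginal per window: no smoothness is shared across
  windows, so very small per-window samples give ragged corridors; that is
  the price of the method's transparency.
* The marginal-only prior transfer is information-preserving only in the
  orthogonalized parameterization; users supplying their own designs should
  keep the centering (the constructor does it by default).
* GeoJSON output inverse-projects NAD83 plane coordinates and labels them
  WGS84-equivalent; the metre-level datum difference is far below sighting
  accuracy.
* The pipeline estimates *where* the corridor is and how it moves — it does
  not attribute causes, model habitat, or forecast.
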