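---
title: "Methods: GPS collar analysis of grazing cattle behavior"
author: "grazetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS collar analysis of grazing cattle behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(grazetrack)
```

## The problem

Pasture weed encroachment — here, spiny pigweed spreading through
bermudagrass paddocks — changes how cattle use a pasture: animals walk
farther, rest less, and avoid weed patches. Quantifying those changes
requires second-by-second GPS collar records over weeks, turned into a small
set of interpretable metrics: daily distance traveled, rate of travel,
activity budgets (resting / grazing / traveling), zone occupancy, and
landscape preference. `grazetrack` implements that processing chain for a
randomized complete block grazing trial (three encroachment levels x four
blocks, two tester steers per ~1.3 ha paddock, 1 Hz fixes over 21-day
collar periods), plus a synthetic herd generator so every stage can be
validated against known ground truth.

## Trajectory processing

**Projection.** Geographic fixes are projected to UTM meters with a
6th-order Krüger-series transverse Mercator (WGS84), accurate to well under
a millimeter inside a zone; the zone can be fixed or derived from the mean
longitude. Synthetic data live directly in a local planar frame and bypass
the ellipsoid entirely.

**Geofencing.** Fixes outside the paddock boundary polygon (pen-to-paddock
pathways, noise excursions) are removed by a crossing-number
point-in-polygon test. The convention is *closed* everywhere in the
package: points exactly on a boundary are inside, so fence-line fixes are
never lost. Fixes *inside* the paddock are deliberately not filtered for
accuracy — location error is common to all treatments, and removing fixes
would cost far more data than the precision gained.

**Daily segmentation.** Days are local civil days of the study timezone,
split at midnight; daily behavior is diurnal, so civil days are the natural
aggregation unit. A day is flagged excluded when its fix count falls below
`min_coverage` (default 0.8) of the expected count, which naturally drops
collar-recharge days. The threshold is configurable because no completeness
rule is inherent to the data.

**Distances and speeds.** Step distances are planar Euclidean
(Pythagorean) lengths between sequential positions, summed per day
(m/day). Rate of travel is distance over the *time taken to change
position*: consecutive identical positions are collapsed to the first, so
a stationary run contributes its full elapsed time to the step that ends
it. This is also why mean rates exceed `distance / 1440`: stationary time
is excluded from per-step denominators. Both the moving-time and the
elapsed-time estimator are computed and labeled, since published "rate of
travel" values rarely state which was used. A collapsed stationary run is
*not* a recording gap: gap detection (default `max_gap_s = 300`) is judged
on the raw fix spacing absorbed into each collapsed step, and only steps
spanning genuinely missing fixes are excluded from daily sums.

**Activity classification.** Speeds classify as resting below
2.34 m/min, grazing from 2.34 to 25 m/min inclusive, and traveling above
25 m/min — the cattle calibration in wide use for grazing steers. Band
edges go to grazing because the grazing band is described inclusively
("between") while resting and traveling are strict ("lower than",
"greater than"). All stationary activity, including rumination, is resting
by construction. Budgets are dt-weighted percentages of *classified* time,
not wall-clock time, so dropout days do not distort them. Known
limitation, shared with any GPS-only classifier: slow grazing at a feeding
station is indistinguishable from resting, so resting is overestimated and
grazing underestimated; no correction is attempted.

## Site use

**Zone occupancy** is the fraction of fixes inside each zone polygon
(shade and water-trough zones carry a 10 m round buffer around the surveyed
point, matching the device's sub-10 m error). At a constant fix rate the
fix fraction equals the time fraction; a dt-weighted variant covers
resampled data. Overlapping zones tally independently. Hours per day are
`pct/100 * 24`.

**Landscape Preference Index.** `LPI = time fraction / area fraction`;
1 means use proportional to availability. Only the strip LPIs are fully
reproducible from published numbers (occupancies 37.3% and 29.1% against a
48%/52% area split, giving 0.7 and 0.6); shade and water footprints are
site-specific.

**Kernel density.** Fixes are binned to grid cells (default 1 m) and the
counts convolved with a quartic kernel of 10 m radius — the common
heatmap construction, with the bandwidth matched to the device error.
Gaussian (truncated at 4 sigma) and Epanechnikov kernels are available.
Values are densities per m² scaled so that mass (density x cell area) sums
to the number of fixes; with a grid margin of at least the kernel radius,
mass is conserved to well under 1%. Spatial resolution equals the cell
size, since points are treated at their cell center. Hotspots are cells
strictly above a chosen quantile of the cell values.

## Climate

The temperature-humidity index is
`THI = 1.8 Tdb + 32 - (0.55 - 0.0055 RH)(1.8 Tdb - 26.8)`. The bracketing
follows the standard form of the index: it reproduces the RH-independence
pivot at Tdb = 26.8/1.8 ≈ 14.9 °C, collapses to the Fahrenheit temperature
at saturation, and yields the 74–79 range typical of panhandle-Florida
summer daily means — the band read as light heat-stress load for beef
cattle.

## Study summaries

Animal-day metrics are averaged across the two testers of a paddock (lone
animals are flagged, never silently averaged), assigned to 21-day
evaluation periods, and reduced to paddock-period means. The analysis of
variance is the classical balanced-design sum-of-squares decomposition for

\[ y_{ijk} = \mu + \tau_i + \beta_j + t_k + (\tau t)_{ik} + \varepsilon_{ijk} \]

with treatment, block, period, and treatment-by-period effects, F-tested
against the residual mean square. The decomposition is authored directly
(and cross-checked against `aov` in the test suite) rather than delegated,
because it is the statistical core of the package; a mixed model with year
as a random effect is out of scope, and multi-year data should be analyzed
per year. Treatment means carry an SEM (`sqrt(MS_res / (b p))`) and compact
letters from pairwise t tests on the residual mean square, unadjusted by
default to match the plain "significant at p < 0.05" convention;
`p_adjust` enables a correction. Missing cells are an error — no
imputation. Reported derived statistics (percent distance change,
cross-treatment means, hours per day, LPIs) are rounded as published
conventions dictate: integers for percentages, one decimal for means and
indices.

## The synthetic herd

No collar dataset is public, so the generator is the package's ground
truth. It emulates the data model, not cattle cognition:

- **Bout process.** Behavior alternates among resting, grazing, and
  traveling with exponential bout durations (defaults 1800 / 900 / 180 s);
  the embedded chain is weighted so expected time shares match the target
  budget. When a target daily budget is given (defaults to the
  cross-treatment means 87.2 / 7.6 / 5.2%), each state's drawn durations
  are rescaled so the designed shares are met exactly — the budget is a
  designed quantity, not an estimate.
- **Movement.** Within moving bouts, a correlated random walk:
  wrapped-Cauchy turning angles (concentration 0.6 grazing, 0.9
  traveling), log-normal speeds truncated strictly inside the classifier
  bands when `separable = TRUE` (so classification error is attributable
  to location noise alone); resting is exactly stationary. The fence is
  specularly reflective. On bout switches the walk can be directed toward
  a point in an attractor zone (defaults: shade 0.15, water 0.08), which
  reproduces shade/water hotspots and preference indices above 1.
- **Location error.** Modeled as an isotropic Gaussian bias held constant
  over exponential epochs (defaults: 5 m SD, 600 s mean epoch), not as
  per-fix white noise. Cheap-logger error is dominated by slowly varying
  satellite-geometry and multipath bias; fix-to-fix precision is far finer
  than absolute accuracy — which is the only way 1 Hz collar data can
  classify ~85% of the day as resting, as observed field data do. White
  noise of even 1 m at 1 Hz would classify nearly the whole day as
  traveling. Under this model, 5 m error biases budgets from resting
  toward grazing by a few percentage points and inflates daily distance,
  while coarser resampling deflates it — the two error directions
  (measurement vs interpolation) the literature describes.
- **Study design.** `simulate_study()` emits the full file tree (collar
  CSVs, zone GeoJSON, design and period tables, ground truth) for a 3 x 4
  RCBD with two testers per paddock, with treatment budgets defaulting to
  the published encroachment gradient. Day-level and block-level variance
  components act on the grazing/traveling shares; the paddock-level
  component defaults to zero because a whole-plot random effect would
  invalidate the fixed-effects F test's nominal level — a deliberate
  calibration choice, documented limitation of the fixed-effects summary.
  `simulate_study_metrics()` draws the identical budget model but maps
  budgets to distances analytically, as the fast path for statistical
  calibration.

What the generator does *not* emulate: real bout-duration distributions
(unknown for these steers), weather-coupled behavior, herd interaction,
and terrain. Passing recovery tests therefore demonstrates that the
pipeline measures what the model generates — not that the model is cattle.

## Numerical choices and problem sizes

- Buffers use 64 arc vertices per full circle (area error ≈ 0.16%,
  comfortably inside the 1% analytic tolerance); buffering supports points
  and convex polygons, which covers every buffered feature in a paddock
  layout.
- Point-in-polygon is validated against an independent winding-number
  oracle on random star-shaped polygons (up to 50 vertices), 10^4 points
  per polygon, 100 polygons, with zero tolerated mismatches.
- Parameter recovery runs one simulated day at the native 1 Hz (86,400
  fixes): designed budgets recover within ±1 percentage point with zero
  noise, and daily distance to 1e-6 relative.
- ANOVA calibration uses 2000 null draws on the 3 x 4 x 5 design
  (rejection 0.05 ± 0.02) and 100 study replicates at the default
  treatment contrast for power (≥ 80%); the study replicates use the
  metrics-level generator with 3-day periods.
- The bias experiment uses 20 Monte-Carlo days across noise SDs
  {0, 2.5, 5, 10} m and intervals {1, 10, 60, 300, 600} s.
- End-to-end pipeline tests run a reduced study (two 1-day periods at
  0.1 Hz) through simulate → process → summarize; the full-size defaults
  (21-day periods, 1 Hz) are what the generator emits when asked.

## Limitations

- The fixed-effects ANOVA treats paddock-periods as independent; repeated
  measures on a paddock with a nonzero whole-plot variance need a mixed
  model, which this package deliberately does not fit.
- GPS-only classification confounds stationary grazing with resting.
- Published SEM columns from field data cannot be reproduced without the
  raw dataset; SEMs are validated on synthetic data only.
- Buffering is convex-only; density grids export as ESRI ASCII text
  rasters.
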