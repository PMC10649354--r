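# grazetrack

Trajectory analysis for GPS-collared grazing cattle, built for pasture
trials where behavior — not just performance — is the response. The
motivating setting is weed encroachment (spiny pigweed in bermudagrass
paddocks): encroachment makes cattle walk farther, rest less, and avoid
weed patches, and those effects are measurable from cheap 1 Hz GPS collars
long before they show up in weight gain.

The package covers the full chain:

- **Ingestion & cleaning** — CSV/GPX logger files; sorting, duplicate and
  bad-row handling with audit counts; geofencing to the paddock boundary;
  local-calendar-day segmentation with coverage flags.
- **Movement metrics** — planar (UTM) projection, Pythagorean step
  distances, daily distance traveled (m/day), rate of travel (m/min) over
  position changes.
- **Activity budgets** — speed-threshold classification: resting
  < 2.34 m/min, grazing 2.34–25 m/min (inclusive), traveling > 25 m/min;
  dt-weighted daily percentages.
- **Site use** — zone occupancy (shade, water, pasture strips, with 10 m
  round buffers), Landscape Preference Index
  `LPI = time fraction / area fraction`, and quartic-kernel density
  heatmaps with hotspot extraction.
- **Climate** — temperature–humidity index
  `THI = 1.8·Tdb + 32 − (0.55 − 0.0055·RH)(1.8·Tdb − 26.8)`.
- **Study summaries** — tester averaging, 21-day period assignment, and a
  fixed-effects randomized-complete-block ANOVA
  `y = μ + τ(treatment) + β(block) + t(period) + τ×t + ε`
  with SEMs and mean-separation letters.
- **Synthetic herd** — a semi-Markov / correlated-random-walk simulator
  with exact budget calibration, attractor zones, reflective fences, and an
  epoch-bias GPS error model, so every stage is testable against ground
  truth; plus a bias experiment quantifying measurement vs interpolation
  error in distance estimates.

## Worked example

Simulate one collared animal for a day (85.1 / 8.9 / 6.0% designed budget,
5 m location error), then run the analysis chain:

```r
library(grazetrack)

cfg <- sim_config(target_budget = c(resting = 85.1, grazing = 8.9, traveling = 6.0))
sim <- simulate_trajectory(cfg, seed = 1)
day <- split_days(sim$trajectory)[[1]]

daily_metrics(day)
#>   animal_id paddock_id       date distance_m_per_day rate_moving_m_per_min
#> 1        A1        P01 2022-07-12           6106.144              4.255004
#>   rate_elapsed_m_per_min n_fixes coverage excluded
#> 1               4.255004   86400        1    FALSE

activity_budget(day)
#>   animal_id paddock_id       date resting_pct grazing_pct traveling_pct
#> 1        A1        P01 2022-07-12    76.50024    17.43377      6.065991
```

The designed distance for that budget is ≈ 4,480 m/day; the estimate reads
6,106 m because accumulated location error inflates distance — the
classic overestimation of high-frequency GPS sampling, which
`bias_experiment()` quantifies. Likewise part of the designed resting time
is read as grazing (76.5% vs 85.1%), the documented direction of
GPS-only classification error.

Zone occupancy and preference:

```r
zone_occupancy(day, cfg$paddock$zones)
#>                 zone n_inside pct_of_day      hours
#> 1              shade     1420   1.643519  0.3944444
#> 2              water     6686   7.738426  1.8572222
#> 3         weed_strip    24212  28.023148  6.7255556
#> 4 bermudagrass_strip    56898  65.854167 15.8050000

lpi(0.0774, cfg$paddock$zones$water$area_m2 / 13000, "water")$lpi
#> [1] 3.208  # strong preference for the small water-trough zone
```

And the heat-stress index for a typical Florida summer day:

```r
thi(27, 80)
#> [1] 78.202   # inside the 74-79 "light load" band
```

A full trial (3 treatments × 4 blocks × 2 testers) runs through the staged
pipeline, from the shell if preferred:

```sh
Rscript inst/cli/grazetrack.R simulate --out data --seed 1
Rscript inst/cli/grazetrack.R process --data data --out processed
Rscript inst/cli/grazetrack.R summarize --data data --processed processed --out summary
```

which writes daily metric tables, activity budgets, zone occupancies,
density rasters (`.asc`), treatment × period means with ANOVA tables, and
the derived statistics (percent distance change, cross-treatment activity
means, hours per day, LPIs).

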