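# grazeproxy

Quantifying livestock grazing intensity in fenced household pastures from
repeated drone surveys, using dung pats as a countable proxy.

Grazing intensity — how much livestock occupancy a patch of pasture receives
over a period — is hard to measure in free-grazing systems. `grazeproxy`
implements a pipeline built around two ideas from UAV-based rangeland
monitoring on alpine yak pastures:

1. **An adapted kernel density estimator.** The herd is photographed from the
   air once per hour on a handful of randomly chosen days per month. Each
   individual in a snapshot deposits one *yak·hour* of occupancy mass, spread
   over the surrounding area by a radially symmetric triangular kernel

   K(d) = 3 / (π h²) · (1 − d/h)   for d < h, else 0,

   with bandwidth h = 300 m (the hourly activity radius of grazing yaks), so
   each kernel integrates to exactly one yak·hour. Snapshots are weighted by
   `grazing_hours / snapshots_per_day`, and the sum over monitored days is
   scaled by the adjustment factor A = `days_in_month / n_monitored_days`,
   giving monthly grazing-intensity rasters in yak·h·m⁻² (default 1 m
   resolution).

2. **Calibration against dung density.** Dung pat counts in fixed-waypoint
   image footprints are converted to densities (pats·m⁻²) and regressed on
   the grazing intensity accumulated over windows of k = 1…6 consecutive
   months ending at the survey month. The package fits every feasible
   (dung month, window) pairing by OLS, reports slope, intercept, R² and the
   slope F-test p-value, tests how R² grows with accumulation duration, and
   inverts a calibration to predict intensity from dung density alone.

Because the field data are not publicly deposited, the package ships a
seeded virtual-pasture generator (`run_virtual_study()`) emulating the study
system — a 113.64 ha pasture, a 278-head cohesive yak herd concentrated
around a campsite, Poisson dung deposition, exponential monthly decay with
riverbed washout, and flight-height-dependent detection (100% at 2 m,
93.16% at 20 m) — so every stage is testable end to end against a known
ground truth.

## Worked example

```r
library(grazeproxy)

# UAV footprint geometry: 1/2.3" sensor at 20 m flight height
footprint_dimensions(camera_profile("phantom3pro"), 20)
#>  width_m length_m
#> 34.18283 25.65097

# a full virtual grazing season, deterministic given the seed
study <- run_virtual_study(sim_config(seed = 1))
study
#> <virtual_study> 278 yaks, 113.64 ha, months May Jun Jul Aug Sep Oct, seed 1
#>   141 retained waypoints, 846 count records, grid 107 x 107 @ 10 m

cal <- calibrate_study(study)
head(cal$table[order(cal$table$k), ], 6)
#>   k dung_month   n slope intercept r_squared  p_value degenerate
#> 1 1        May 141 1.114  -0.01621     0.933 2.44e-83      FALSE
#> 2 1        Jun 141 1.725  -0.01821     0.831 1.91e-55      FALSE
#> 3 1        Jul 141 2.061   0.00472     0.751 9.30e-44      FALSE
#> 4 1        Aug 141 3.018  -0.04972     0.797 4.75e-50      FALSE
#> 5 1        Sep 141 3.306  -0.01207     0.853 9.98e-60      FALSE
#> 6 1        Oct 141 4.163  -0.07164     0.857 1.43e-60      FALSE
```

Each row is one OLS fit of waypoint dung density (pats·m⁻²) on cumulative
grazing intensity (yak·h·m⁻²) for one accumulation window. The same-month
(k = 1) slopes rise from May to October because dung standing crop keeps
accumulating while a single month's intensity does not — the signature that
motivates pairing dung with *cumulative* intensity.

```r
cal$trend[c("slope", "r_squared", "p_value")]
#> $slope      0.0178
#> $r_squared  0.310
#> $p_value    0.00879
```

R² increases with accumulation duration k (positive trend slope): the longer
dung is allowed to accumulate, the better its density indicates grazing
intensity. Inverting the strongest calibration (October density vs the
full-season window) turns a measured dung density into an intensity
estimate with a first-order prediction interval:

```r
predict_intensity(cal$results[["k6_Oct"]], density = 0.5)
#>   density intensity lower upper clamped
#> 1     0.5     0.837 0.486  1.19   FALSE
```

A thin CLI wrapping the same functions lives at `inst/cli/grazeproxy.R`
(subcommands `simulate`, `intensity`, `calibrate`).

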