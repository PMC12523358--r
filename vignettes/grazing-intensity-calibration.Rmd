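---
title: "Estimating grazing intensity from dung proxies: model, simulator and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating grazing intensity from dung proxies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grazeproxy)
```

## The estimation problem

A fenced household pasture is grazed by a single herd that is penned at
night and released to graze by day. The quantity of interest is **grazing
intensity**: the cumulative occupancy, in yak·hours per square metre, that
each location receives over a month or a season. Two data streams are
available: (i) hourly aerial snapshots of the whole herd on a few randomly
chosen days per month, and (ii) dung pat counts inside fixed-waypoint image
footprints revisited monthly. The first stream yields a direct but sparse
estimate of intensity; the second is cheap and dense but only a proxy. The
package estimates intensity from the first stream, calibrates the proxy
against it, and quantifies when the proxy is trustworthy.

## The adapted kernel density estimator

Classical KDE normalizes to a probability density. Here the kernel is
re-interpreted physically: one individual photographed at one hour
contributes exactly **one yak·hour** of occupancy, spread over its
surroundings. We use the radially symmetric triangular (conical) kernel

$$K(d) = \frac{3}{\pi h^2}\left(1 - \frac{d}{h}\right), \qquad d < h,$$

whose integral over its support is exactly 1. The literature this design
follows names the kernel family and its bandwidth but not the 2D form; the
cone is the natural radially symmetric extension, and the normalizer
$3/(\pi h^2)$ is what makes the unit-mass interpretation hold (verified by
quadrature in the test suite). The bandwidth default, $h = 300$ m, is the
reported hourly activity radius of grazing yaks; it is a biological scale,
not a statistical smoothing choice, and no bandwidth selection is offered.

A monthly surface is assembled as

$$\hat{G}_m(x) = \underbrace{\frac{D_m}{|M_m|}}_{\text{adjustment } A}
  \sum_{d \in M_m} \sum_{s \in d} \frac{H_d}{n_d} \sum_{i=1}^{N} K(\|x - x_{i,s}\|),$$

where $M_m$ are the monitored days of the month, $D_m$ the days in the
month, $H_d$ the grazed hours and $n_d$ the snapshots of day $d$. Each
day's weighted snapshot sum estimates that day's total yak·hours; the
adjustment factor $A = D_m/|M_m|$ scales the monitored days up to the full
month. The exact published form of this compensation is in prior work that
the source study cites without reprinting; the reconstruction above is the
simplest one that preserves the yak·hour unit and is pinned by an
arithmetic oracle in the tests (stationary herd of $N$, 4 of 30 days
monitored, 12 snapshots over 12 grazed hours $\Rightarrow$ total mass
$N \cdot 12 \cdot 30$).

Numerical choices:

* Kernels are evaluated at **cell centres** (midpoint rule), not
  cell-integrated; at 1 m cells the discretization error on a kernel's mass
  is far below the 1% test budget, and total mass at 0.5 m and 2 m cells
  agrees within 2%.
* **No edge renormalization** by default: a kernel centred within $h$ of
  the boundary deposits less than one yak·hour inside the grid. This is
  deliberate — the mass-conservation contract is stated for interior
  animals, and silently renormalizing would bias boundary cells relative to
  the published maps. The truncation is documented rather than corrected.
* Maps default to **1 m resolution**. Whole-season simulation studies use
  10 m cells: with a 300 m bandwidth the surface varies on scales of
  hundreds of metres, so a 10 m grid resolves it essentially exactly (the
  refinement invariant above), at a hundredth of the cell count.
* Rasters serialize as ESRI ASCII grids (nodata −1) with a JSON sidecar
  carrying the period, bandwidth and adjustment factor.

## The virtual pasture

No raw field data are deposited, so the package carries a generator whose
defaults *are* the study conditions: a square 113.64 ha pasture; a campsite
concentrator offset from the centre; 278 yaks; May–October season; 4–8
randomly chosen monitoring days per month; 12–14 hourly images per day
(equal to the grazed hours that day, as the imaging schedule followed the
herder's); a 50 m fence buffer and 150 m campsite buffer excluded from
sampling; detection probability 1.0 at 2 m and 0.9316 at 20 m flight
height, with no interpolation between heights; and GPS drift of the
footprint centre uniform in a 2 m disc per visit (the upper end of the
reported 1–2 m drift).

**Movement.** The herd grazes as a *cohesive group*: each hour the herd
centre is drawn from the campsite-centred distance-decay field
$p(x) \propto \exp(-\mathrm{dist}(x, \text{campsite})/\lambda)$ restricted
to the pasture, blended with the previous hour's centre with weight
$\rho = 0.5$ for positional autocorrelation, and individuals scatter around
the centre with s.d. 30 m. Cohesion is not incidental: a single hourly
aerial image can cover the entire herd, which bounds the herd's spread to
roughly one image footprint at survey height, and it is what makes monthly
intensity estimates from 4–8 days genuinely noisy and month-specific —
the statistical regime in which accumulating dung over longer windows
visibly improves the proxy. An independent-draws model (each yak placed
separately from the field) produces month surfaces correlated at
$r > 0.999$ and erases that regime. The first and last hour of each day
use $\lambda/2$, so days start and end nearer the campsite. The default
$\lambda = 300$ m matches the hourly activity radius; the marginal
distribution of positions retains the radial gradient that the campsite
system is known to generate.

**Deposition, decay, observation.** Per yak·hour the pat count is
Poisson(`deposition_rate`); pats land at the yak's position with 0.5 m
Gaussian jitter clipped to the pasture. The defaults
`deposition_rate = 1` pat·yak⁻¹·h⁻¹ (of the order of a dozen defecations
per grazing day) and `decay_rate = 0.2` month⁻¹ (slow decay: ~82% monthly
survival) are free parameters — the source study reports no rates — so all
quantitative acceptance checks are *recovery* checks of configured values,
never absolute levels. Month-to-month survival is $e^{-\delta}$,
multiplied through `riverbed_decay_multiplier` for pats in the optional
riverbed strip (washout); a pat is always present in its deposition month
(age-0 survival is 1). Dung density at a month is **standing crop**: every
pat deposited since season start that has not yet decayed. Observed counts
are Binomial(true count, p(height)) plus Poisson false positives; with the
false-positive rate at its default 0, observed counts are stochastically
below truth.

Every stage draws from its own named substream (design, movement,
deposition, decay, detection) derived from the master seed, so a stage can
be re-run independently and the whole study is bit-reproducible from the
seed.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about field data: vegetation growth and occlusion of pats
(a suspected cause of densities dropping to zero mid-season), misdetection
of old dung or bare soil, seasonal changes in herder strategy or forage
quality, spatially correlated decay micro-environments beyond the single
riverbed strip, and any real image-processing errors. The simulator can
imitate some of these phenomenologically (detection drop, smaller
$\lambda$, faster decay) but asserts no single cause.

## Calibration

Waypoint dung densities (counts over the footprint area) are paired with
cumulative intensity over every window of $k$ consecutive months ending at
the survey month; over a May–October season this gives 6, 5, 4, 3, 2, 1
pairings for $k = 1..6$. All feasible windows are enumerated;
study-specific exclusions (e.g. dropping one month's same-month fit, or
waypoints whose footprints are dominated by riverbed at the 0.5 overlap
threshold — ties excluded) are input flags, not hard-coded rules. Each
pairing is fit by OLS of density on intensity; the p-value is the slope
F-test; no multiple-testing correction is applied (matching the source
analysis), and reports state the number of tests run. Fits with zero
density variance (all-zero counts) are flagged degenerate and excluded
from the R²-vs-k trend rather than entered as $R^2 = 0$: the trend is
about fitted relationships, and zero-variance "fits" are not fits.

The R² trend is itself an OLS of per-pairing R² on $k$ (replicated points
per $k$). Flight-height accuracy comparisons run Shapiro–Wilk per group
and Levene's test at $\alpha = 0.05$, then one-way ANOVA when assumptions
hold and a Wilcoxon rank-sum fallback otherwise, reporting which path ran;
fully tied groups return $p = 1$ with a flag. Accuracy fractions are
analysed untransformed by default (an arcsine-square-root option exists).
Inverse prediction uses the first-order estimate
$(\text{density} - b_0)/b_1$ with an interval of $\pm z \cdot s/b_1$;
negative estimates are clamped to zero and flagged, and a non-positive
slope is refused outright because it contradicts the proxy premise.

Two open analysis choices were resolved as follows. Regressions are fitted
*per (month, window) pairing* across waypoints (matching the per-panel
presentation of the source figures) and aggregated afterwards for the
trend. And parameter-recovery analyses pair densities with the simulator's
**true occupancy raster** (binned yak·hours of every simulated hour), not
the KDE estimate: the 300 m kernel deliberately flattens the radial
gradient, so the KDE-paired slope is attenuated by design, while the
deposition mechanism itself is linear in true occupancy — with decay off
and detection perfect, the fitted slope recovers the configured deposition
rate within a few percent.

## Problem sizes and tolerances

The unit tests run the geometry and kernel contracts at closed-form or
quadrature precision (1e-9 to 1e-3 as appropriate), mass conservation on
1 m grids over 700 m windows, and pipeline round-trips on a reduced study
(15 yaks, 3 months, 50 m cells). The end-to-end distributional checks use
the full default conditions: 278 yaks over the whole season at 10 m cells,
20 seeded replicates for the R²-trend sign property, and 12,000 simulated
pats for the detection-fraction check (3 Monte-Carlo-SE budget). Known
limitations: rectangular pastures only for exact effective-area geometry
(generic polygons fall back to grid counting), axis-aligned footprints
(UAV yaw is not recorded by the fixed-point protocol), no spatial
correlation in regression errors, and no Bayesian or errors-in-variables
calibration.
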