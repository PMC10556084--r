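---
title: "vinecast methods: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vinecast methods: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinecast)
```

`vinecast` chains four model layers — solar geometry, row-shadow light
interception, canopy transpiration regression, and a daily soil water
balance — and couples them with a binary-event classification harness for
phenology dates. This vignette documents the science in each layer, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## Solar geometry

Solar declination uses the Spencer trigonometric series (seven Fourier
terms in the day angle), which is accurate to a few hundredths of a degree
and verified in the test suite against an independent implementation of
the NOAA solar-calculator algorithm. Elevation and azimuth follow the
standard spherical-astronomy formulas in **local solar time**; conversion
from civil time (longitude, equation of time, DST) is deliberately left to
the I/O layer so that the physics layer stays timezone-free.

Day length is the time the sun spends above a configurable altitude
threshold, default **-0.833 degrees** (atmospheric refraction plus the
solar half-disc — the convention behind published sunrise/sunset tables).
With this default, 20 June at 45.1 N gives 15 h 38 min, matching
almanac values to the minute; with a zero threshold the day is several
minutes shorter. The threshold is exposed because different applications
(photoperiod biology vs. shadow geometry) legitimately want different
horizons.

Two numerical caveats, both encoded in the tests rather than hidden:

* the hemispheric complement `day_length(lat) + day_length(-lat) = 24 h`
  is exact only at the geometric horizon (threshold 0); the refraction
  convention lengthens the day in both hemispheres;
* azimuth comparisons against an independent oracle are made only where
  azimuth is well-conditioned (elevation below 60 degrees, latitude at
  least 15 degrees from the equator). Near the zenith, and over the
  equator at the equinoxes, a 0.1-0.2 degree difference between
  declination series is amplified arbitrarily in azimuth; in those
  configurations azimuth hardly affects shadow geometry anyway because
  `cot(elevation)` is near zero.

Clear-sky irradiance is a simple transmittance model: direct-normal
irradiance is the extraterrestrial flux attenuated as
`clearness ^ airmass` (Kasten-Young air mass, altitude-scaled), with
diffuse light a fixed fraction of the direct-horizontal beam. Defaults:
`clearness = 0.72`, `diffuse_fraction = 0.18`, typical of clear summer
days in temperate wine regions. This layer is a *stand-in for measured
incident light* — an operational deployment would feed radiometer or
reanalysis data instead — and is therefore kept deliberately simple:
no turbidity climatology, no spectral model. Irradiance is expressed as
photosynthetic photon flux (umol m-2 s-1) using the daylight conversion
4.6 umol J-1 over the PAR band and a PAR fraction of 0.45 of total
shortwave; both constants are exported.

## Row-shadow canopy light interception

The vine row is an opaque rectangular slab of thickness `canopy_width`
and height `canopy_height`, infinitely long (end effects ignored), the
natural idealisation of a trained vertical-shoot-positioned canopy wall.
The direct-beam shadow band across the alley has width

```
width = canopy_width + canopy_height * cot(elevation) * |sin(sun_az - row_az)|
```

and total canopy light interception is the shaded fraction of the alley,
`TCLI (%) = 100 * min(width / row_spacing, 1)`. Assumptions worth
stating:

* **Opacity.** Canopy porosity is ignored; the slab casts a full shadow.
  This matches how shaded area is measured under dense walls and keeps
  the model free of a porosity parameter that could not be estimated from
  the inputs the tool requires.
* **Direct beam only.** Diffuse interception is not separately modelled;
  TCLI is defined from the shadow footprint.
* **Base height.** On flat ground the canopy base offset shifts the
  shadow sideways without widening it, so it does not enter the fraction.
* **Night and low sun.** When the sun is below the horizon the shadow is
  undefined and the fraction is reported as 1 (no direct beam reaches the
  alley floor); at low sun angles the width exceeds the spacing and TCLI
  pins at 100%, producing the characteristic U-shaped diurnal profile
  with, for a NE-SW row at 45 N in July, a minimum in the early
  afternoon.
* **Slope.** Sloped ground is handled by rotating the sun vector into a
  terrain-aligned frame before projection. Flat ground is the
  quantitatively tested configuration; sloped ground is covered by
  invariant tests (bounds, composition identity) only.

## Canopy transpiration regression

Whole-canopy transpiration y (mmol H2O/s) is regressed on x1 = total
direct light (umol m-2 s-1), x2 = air VPD (hPa) and x3 = TCLI (%). The
selected form is the **pure quadratic without intercept or linear
terms**:

```
y = a*x1^2 + b*x2^2 + c*x3^2 + d*x1*x2 + e*x1*x3 + f*x2*x3
```

so the prediction at the origin — no light, no evaporative demand, no
interception — is structurally zero. Linear candidate models carry an
intercept. `compare_tc_models()` fits every linear and quadratic
candidate over variable subsets and ranks by R-squared (uncentred for the
intercept-free quadratic), the workflow under which the three-variable
quadratic is selected on field calibration data.

Three published day-specific coefficient sets ship as named fixtures
(`tc_printed_models()`). Two documentation-level choices:

* **VPD unit: hPa.** With VPD in hPa the published coefficients evaluated
  at realistic mid-afternoon inputs (x1 = 1500, x2 = 25 hPa, x3 = 30)
  give about 6.2 mmol/s = 399 g/h, the magnitude of measured clear-day
  peaks; in kPa they would be off by two orders of magnitude. kPa inputs
  are converted at the function boundary (`vpd_unit = "kPa"`).
* **The third set's trailing term.** As published, the 1 August equation
  ends with two x1*x2 cross terms — evidently a transcription slip for
  x2*x3. Both readings are provided (`correct_typo = TRUE` reassigns the
  trailing coefficient to x2*x3; the default sums the duplicates into
  x1*x2) and both are exercised in tests.

Raw polynomial predictions can go negative off the calibration domain;
they are clamped to zero with a warning and a `clamped` attribute, rather
than silently propagated into the water balance.

Unit conversions are centralised: mmol/s to g/h via the molar mass of
water (1 mmol/s = 64.854 g/h), then per-vine daily litres
(`rate * day_length / 1000`), per-area mm (`L/vine * density / 10000`)
and per-leaf-area litres. Applied to mean diurnal rates of 229, 268 and
224 g/h with day lengths 15 h 38 min, 15 h 34 min and 14 h 43 min at
4000 vines/ha and 3.37 m2 leaf area, the chain yields 3.58, 4.17 and
3.30 L/vine/day, 1.32-1.67 mm/day and 0.98-1.24 L/m2 — the published
summary of those inputs reports 3.27 (hence 1.31 and 0.97) for the third
day, about 1% away from what its own printed inputs produce; the package
reports the recomputed values and the tests document the discrepancy
explicitly rather than absorbing it into a loose tolerance.

## Soil water balance and drought warnings

Plant-available water capacity comes from the **Saxton & Rawls (2006)**
pedotransfer equations: volumetric moisture at 1500 kPa (wilting point)
and 33 kPa (field capacity) as quadratic-corrected linear functions of
sand, clay and organic matter, scaled by rooted depth (default 1 m) into
`saw_capacity_mm`. The equations are implemented natively (no R package
on CRAN provides them) and oracle-tested against an independent writing
of the published regressions.

The daily balance is
`reservoir' = clamp(reservoir + P - ETs - Tc, 0, capacity)`: rain in
excess of capacity leaves immediately as deep percolation (no runoff
routing), and demand beyond supply is truncated and reported as unmet
demand instead of driving the reservoir negative. Mass is conserved to
machine precision: over any window,
`delta reservoir = sum(P) - sum(ETs) - sum(Tc) - sum(drainage) + sum(unmet)`,
and the test suite asserts a residual below 1e-9 mm over a synthetic
decade. The season starts with a full profile at the configured start
date (winter recharge), adjustable via `initial_fill`.

Floor evapotranspiration follows piecewise-linear seasonal curves
anchored on closed-chamber measurements: tilled or herbicide-strip soil
at 1.6 mm/day in the growing season; active grass (spontaneous or
pre-termination winter cover crop) at 2.7 mm/day; after the cover crop is
rolled, the mulch decays from 2.0 mm/day at +1 day (a 26% drop) through
0.5 mm/day at +14 days to the 0.3 mm/day winter baseline by +30 days.
All classes share that winter baseline. The measured anchor "0.5 mm/day
two weeks post-termination" is read as an absolute rate (the level the
decay passes through), the reading consistent with the diurnal chamber
figures. Between anchors the interpolant is linear — the measurements
constrain only the anchor points, and a smoother curve would add shape
the data cannot support. Zones combine by ground-area share alone;
whether shading by the canopy should down-weight under-row zones is not
resolvable from the available measurements, so it is not attempted.

Warnings follow the stoplight convention on the percentage of available
water remaining: **green** above 60%, **yellow** from 60% down to 40%,
**red** at or below 40%. Both boundary points are assigned to the more
severe class — for a warning system the conservative reading of an
ambiguous band specification is the defensible one. Because analytic
test scenarios land exactly on these boundaries, the seasonal driver
rounds the percentage at the ninth decimal before classification,
suppressing floating-point dust without affecting any physically
distinguishable state. Warnings are exported as an append-only log of
state transitions, not a per-day dump: the alert chronology is the
product.

## Phenology: windowed binary-event classification

Each day inside a stage-specific window — budburst DOY 65-100, flowering
140-175, veraison 190-230 — becomes one classification row, labelled 1
only on the observed event date of its site-year. The features are
as-of-date values: cumulative growing degree days (base 10 degC from
1 January), cumulative radiation, cumulative FAO-56 Penman-Monteith
reference ET, the day's Tmax/Tmean, soil temperature (or, when absent,
the previous day's Tmean as a thermal-inertia proxy), VPD (Tetens),
relative humidity, wind and precipitation.

Design choices in the harness, each genuinely open and settled as
follows:

* **Correlation screen reference.** Features are screened by Pearson r
  against the event DOY with one point per site-year, |r| > 0.3 retained.
  By default the screened feature is sampled at a **common reference day
  (the day before the window opens)** rather than at each site-year's own
  event date: sampled at the event date, every cumulative feature
  correlates with DOY almost mechanically (a cumulant grows with elapsed
  time), masking the climate signal. Sampled at a fixed date, the
  correlation measures what differs between site-years — under a
  thermal-time truth, cumulative GDD then dominates the ranking. The
  event-date variant remains available (`ref_doy = NULL`).
* **Split before resampling.** The 80:20 split (or grouped holdout of
  whole site-years, mirroring held-out vineyard units) happens first;
  over/under-sampling touches only the training partition. Resampling
  before splitting would leak duplicated positives across the partition
  boundary and inflate test metrics.
* **Date extraction.** The predicted date is the mean of all in-window
  days whose probability reaches the reliability threshold (default 0.5,
  configurable), rounded to a whole day; if no day qualifies the
  site-year yields an explicit no-prediction, which RMSE scoring excludes
  and counts. Averaging (rather than arg-max) is robust to the plateau of
  near-equal probabilities that tree ensembles produce around the event.
* **Learners are pluggable.** Gradient-boosted trees (default), random
  forest, SVM and k-NN sit behind one fit/predict closure interface; the
  package's contribution is the harness — windows, features, screening,
  resampling, extraction, metrics — not the learners, which come from
  xgboost, randomForest, e1071 and class.

Metrics are computed from the confusion matrix at the chosen threshold:
precision TP/(TP+FP), recall TP/(TP+FN), accuracy, and
F1 = TP/(TP + (FP+FN)/2); AUC is threshold-free, computed by the rank
(Mann-Whitney) statistic with ties counted one half and cross-checked in
tests against both a brute-force concordant-pair enumeration and pROC.
Leave-one-out cross-validation provides the validation phase; a learner
failure on a fold marks the fold failed and the run continues.

## The synthetic-data generator

The generator exists so that every pipeline stage runs and is tested
without external downloads. It emulates a northern-Italian hillside
vineyard network: latitude 44-45.5 N, altitude 27-430 m, annual mean
temperature 13.5 degC with a 10.5 degC seasonal amplitude peaking at DOY
200, 2 degC day-to-day noise, beta-distributed daily clearness scaling a
clear-sky radiation integral, two-state precipitation occurrence (25%
wet days) with gamma amounts, humidity raised on wet days, and a
30-minute sub-daily grid whose daily aggregates match the daily series by
construction. Vineyard geometries are drawn uniformly inside the
envelopes spanned by trained-wall vineyards of the region (spacing
2.0-3.4 m, canopy 0.9-1.4 m by 0.30-0.50 m).

Phenology truth is a pure GDD-threshold rule: the event falls on the
first day cumulative GDD reaches the stage threshold, plus rounded
Gaussian jitter (sd 2 days) emulating the two-day scouting interval of
field phenology surveys. The default thresholds (budburst 30, flowering
420, veraison 1150 degC day) place events inside the standard stage
windows for the default climate; the low budburst threshold mirrors how
small and variable the heat sums at bud swelling are in field data.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: temperature autocorrelation beyond the seasonal
cycle, drought persistence, chilling/dormancy effects on budburst,
cultivar differences, observation bias in visual scoring, and any
coupling between phenology and water status. End-to-end recovery of a
planted GDD rule (flowering RMSE about 2.2 days over eight held-out
site-years at the default settings) demonstrates that the harness is
correct and leak-free, not that field RMSEs of that size are attainable;
published benchmarks on real vineyard networks sit in the 2-9 day range
depending on stage, and reproducing them would require the underlying
per-vineyard weather records, which are not redistributable here.

## Problem sizes and runtime

The shipped tests and the acceptance script use problem sizes chosen to
exercise every code path at interactive speed: 40 synthetic site-years
for the end-to-end phenology experiment, a synthetic decade (3650 days)
for mass-conservation checks, 500 observations for noisy coefficient
recovery, 200 random score sets for the AUC oracle, and minute-scale
scans for profile-minimum checks. The full suite runs in well under a
minute on one core.

## Known limitations

* The clear-sky layer has no turbidity or cloud model; operational use
  should feed measured radiation.
* The water balance is single-layer: no root-uptake profile, soil water
  redistribution or runoff routing, and no irrigation scheduling.
* Transpiration is empirical; the quadratic is trustworthy only inside
  its calibration domain, and extrapolation is clamped, not modelled.
* TCLI ignores canopy porosity and mutual shading beyond the adjacent
  alley.
* Phenology carries no dormancy/chilling sub-model, and classifier
  performance on synthetic data bounds nothing about real vineyards.
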