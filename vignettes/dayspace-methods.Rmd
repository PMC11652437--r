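---
title: "Methods: day-level activity-space exposure and MVPA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: day-level activity-space exposure and MVPA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`dayspace` implements a day-level exposure-outcome pipeline for intensive
longitudinal designs that pair smartphone GPS with hip-worn accelerometry:

1. **Activity spaces.** Each valid GPS day (10-s epochs) becomes a
   *time-weighted surface* on a 50-m analysis grid: cell values are the
   fraction of the day's observed time attributable to the cell, so they
   sum to 1. The primary method is kernel density estimation with a 250-m
   bandwidth; a daily path area (route buffer) and residential buffers
   (euclidean or street-network service areas at 800/1600 m) are provided
   for sensitivity analysis.
2. **Exposure metrics.** Four gridded environmental layers — street-level
   greenspace percentage, walking distance to the nearest park entrance, a
   binary park/open-space indicator, and a walkability index (1-20) — are
   overlaid on the daily surface. Continuous metrics are the weighted sum
   `sum_c w_c v_c`; the park metric is binary: *any* cell with positive
   time weight that is a park cell.
3. **MVPA.** 10-s accelerometer counts are screened for non-wear (zero
   runs strictly longer than 60 min) and day validity (at least 10 h of
   wear); wear epochs are classified as moderate-to-vigorous activity when
   the predicted energy expenditure, `METs = 1.439008 + 0.000795 x cpm`
   evaluated at the epoch's per-minute rate (counts x 6), reaches 4 METs.
   Day-level MVPA minutes are the MVPA epoch count divided by 6.
4. **Models.** Day-level `log(MVPA + 1)` is regressed on all four exposure
   metrics simultaneously, each split by person-mean centering into a
   between-subject (BS) term (person mean, centered on the grand mean of
   person means) and a within-subject (WS) term (day deviation), plus a
   covariate roster, with a random intercept per participant. Estimates
   are exponentiated after Wald-interval construction on the log scale and
   read on the multiplicative scale. The null (intercept-only) model gives
   the ICC. Effect modification adds one exposure x modifier product term;
   simple slopes at modifier levels use the delta method.

## Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| grid cell | 50 | m | absorbs smartphone GPS noise in urban canyons |
| KDE bandwidth | 250 (100 in sensitivity) | m | several city blocks: visual exposure plus nearby destinations |
| daily-path radius | 250 | m | matched to the KDE bandwidth for comparability |
| residential radii | 800, 1600 | m | 5-10 and 15-20 min walks |
| GPS validity | >= 6 h coverage after imputation | h | days below this are dropped; exactly 6 h is valid |
| non-wear | zero run > 60 min (strict) | min | exactly 60 min of zeros is still wear |
| accelerometer validity | >= 10 h wear | h | exactly 10 h is valid |
| cut point | 4 METs, intercept 1.439008, slope 0.000795 | METs, cpm | adult waist-worn count calibration |
| epoch | 10 | s | native logging resolution of both devices |

## Numerical and design choices

**Kernel and discretization.** The kernel family is the quartic (biweight)
`K(d) ∝ (1 - (d/h)^2)^2`, the kernel used by the desktop GIS tools common
in this literature; a truncated Gaussian is config-switchable. Kernels are
evaluated at cell centers rather than integrated over cells: at a 50-m
cell against a 250-m bandwidth the discretization error is small relative
to GPS noise. Each epoch's kernel values are normalized to sum to 1 over
in-grid cells *before* accumulation, so an epoch near the grid edge still
contributes exactly one epoch of time and edge clipping cannot distort
relative weights; the final surface is renormalized exactly.

**Half-open cells.** Cell membership is everywhere a cell-center test with
half-open intervals (closed south/west, open north/east), so boundary
points belong to exactly one cell and adjoining polygons never
double-count.

**Gap imputation.** The upstream study imputed GPS gaps with an
unpublished algorithm; the package ships a documented stand-in. A gap
bounded by fixes within 100 m is treated as a dwell and filled with the
earlier position up to 240 min; other gaps up to 10 min are linearly
interpolated; anything longer, and all leading/trailing missingness, stays
missing. The filler never moves observed fixes, is idempotent, and can
only increase coverage. All three thresholds are exposed.

**Epoch-level classification.** MVPA is classified on 10-s epochs with the
count rate scaled by 6, not on re-integrated 60-s epochs; whether the
original processing re-integrated is unstated, so the choice is recorded
here and the constants are overridable. The 4-MET boundary is read
inclusively (>= 4); since `(4 - 1.439008)/0.000795` is not an integer
count rate, no integer count sits exactly on the boundary and the
inclusive/strict choice cannot change a classification.

**Zero-MVPA days and the log.** The outcome transform is `log(y + 1)`:
defined at zero, exact at zero, and invertible (`exp(x) - 1`) for
reporting trajectories in minutes. The offset is a package decision (the
source analysis does not state one) and is configurable.

**Nodata under the surface.** The street-greenspace layer is defined only
within 25 m of walkable streets. Time weight falling on undefined cells is
renormalized over defined cells by default (the variable simply does not
exist off the street network); treating nodata as zero is available and
changes the metric's meaning to "greenspace exposure assuming none away
from streets". Park distance enters the models per 100 m so all
predictors share a scale.

**Intervals.** Wald z intervals on the log scale, exponentiated
afterwards; ML is the default estimator (REML available). Small-sample
refinements (Satterthwaite, Kenward-Roger) are out of scope; the
null-calibration experiment below quantifies the practical consequence at
the study's size.

**Network distances.** The synthetic street network is a Manhattan
lattice; service areas and walking distances use exact shortest paths
(igraph) including partial edges, and the service area is buffered by one
block width. Network park distance from a cell is the lattice distance
from the cell center's snapped node plus the snap offset — the stand-in
semantics for a precomputed walking-distance raster.

## The synthetic-data generator

No cohort data are shareable, so the generator *is* the study for testing
purposes. It emulates: 55 participants; three waves x four days (two
weekday, two weekend); a 10 x 10 km region with a 200-m street lattice,
1-4 rectangular parks with boundary entrances, tract-like walkability
patches (scores 1-20), and per-segment greenspace percentages; person
covariates drawn to the cohort's descriptive moments (age N(29.0, 6.1)
truncated at 18, education 34.6% some college, parity 29.1% first-born,
BMI 27/35/38% normal/overweight/obese, employment 36.2%, deprivation
1-10, cohesion/safety 1-5); daily temperature N(19.92, 4.40) °C.

Movement is a deliberately minimal two-anchor model: dwell at home, a
street walk at 1.2 m/s to a secondary anchor, an optional park visit
(probability 0.6 per day), return, with N(0, 10 m) position jitter —
just enough structure to exercise every exposure metric, not a realistic
human-mobility model. Missingness is block-structured: contiguous GPS
deletions (some days pushed below the 6-h floor), injected >60-min zero
blocks, and days degraded below 10 h of wear, at configurable fractions.

The outcome model is multiplicative on MVPA minutes:
`log M = mu + b_i + log(1.25) * park_day + log(theta_w) * walkability
deviation + e_ij`, with `b_i ~ N(0, 0.55^2)` and `e_ij ~ N(0, 0.66^2)` —
a 0.41 between-person variance share, and `mu = 3.0` so that mean daily
MVPA lands near 30 min after the log-normal correction. The day's park
label is computed from the generated track by the pipeline's own KDE
exposure operations (one shared code path), and the target is realized
*exactly* as `round(6M)` above-threshold epochs, so clean days round-trip
through the accelerometry module to within one epoch (1/6 min).

Two arms share this truth model: the full arm generates GPS and count
streams and is exercised end to end once per test run; a panel-level arm
(`simulate_analysis_panel()`) draws exposures and outcomes directly and
is used where hundreds of model fits are needed (parameter recovery, CI
coverage, type-I calibration, ICC recovery), at 55 persons x 8 valid
days per replicate — approximately the analyzed study size.

What passing tests do *not* show about real data: the generator has no
spatially autocorrelated GPS error, no activity-type structure (every
MVPA bout is exchangeable), no informative missingness (degradation is
independent of the outcome), rectangular parks, and a lattice street
network. Recovery results demonstrate the estimator machinery, not
robustness to those violations.

## Problem sizes

Unit and property tests run on grids up to 30 x 30 and tracks up to a few
thousand epochs; the recovery experiments use 100 replicates (coverage),
200 replicates (calibration) and 5 replicates (ICC) of 55 x 8-day panels;
the analysis scripts run the full 660-person-day study. The whole test
suite completes in well under five minutes on one core.

## Known limitations

- The time-weighted surface treats every fix equally; dwell-state
  weighting (if the original processing used any) is not implemented.
- The daily-path exposure is uniform over the buffer; only its geometry,
  not a weighting scheme, is specified in the source literature.
- Exposure truth for degraded GPS days is computed from the pre-deletion
  track, so "valid-day" exposure estimates are compared against the full
  day's truth, which is the estimand of interest but not an attainable
  observation.
- The generator does not model attrition (the real cohort's 651 observed
  days for 62 women arise from enrollment and compliance processes it
  does not attempt to reproduce).
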