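---
title: "Methods: integrated monitoring of forest carbon stocks and fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated monitoring of forest carbon stocks and fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcarbon)
```

`forestcarbon` implements an operational chain for monitoring the carbon
balance of forested landscapes: landscape stratification into
eco-functional clusters (EFCs), canopy-height carbon baselines, tower-based
net ecosystem exchange (NEE) with a full uncertainty budget,
satellite-proxy flux maps, a median-ratio extrapolation factor, and a
hash-chained carbon-unit registry. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic fixtures
do and do not establish.

## Eco-functional clustering

Landscape cells carry one categorical field (vegetation class) and two
continuous fields (elevation, canopy height). `fit_kprototypes()` minimises
the mixed dissimilarity

$$d(x, p) = \sum_j (z_j - p_j)^2 + \lambda\,\#\{c : x_c \neq p_c\},$$

by alternating assignment and prototype updates (means for standardized
continuous fields, modes for categorical ones). Choices the method does not
pin down, and how this implementation resolves them:

* **Standardization.** Continuous fields are z-scored before clustering;
  otherwise elevation (hundreds of metres) swamps canopy height (tens).
* **$\lambda$.** Default is half the mean variance of the standardized
  continuous fields, i.e. 0.5 — the common k-prototypes heuristic.
  Overridable.
* **Initialisation.** `k` distinct observations drawn by seed; five random
  restarts keep the best objective. Unbalanced spatial clusters can
  otherwise trap the alternating scheme in a split/merge local optimum.
* **Ties and empty clusters.** Assignment ties break to the lowest cluster
  index; an emptied cluster is re-seeded from the farthest point.

`select_k()` scores each candidate `k` by the mean silhouette under the
same mixed dissimilarity on repeated subsamples (the operational protocol
uses 30 repetitions of 10,000 draws; tests use smaller draws, which is
adequate for well-separated fixtures). `classify_raster()` assigns raster
cells to the nearest prototype; `apply_forest_mask()` removes non-forest
cells (a 10-m land-cover product is aggregated to 30 m by majority rule
first, `aggregate_raster(..., "majority")`); `group_constellations()`
groups contiguous labelled area (8-neighbour connectivity — the
4-neighbour alternative splits blobs joined at corners, which is not how
management units behave) into constellations with an area floor of
50,000 ha.

## Carbon baseline from canopy height

Above-ground biomass density follows the power-law allometry
$AGBD = 1.4535\,CHM^{1.5546}$ (Mg ha⁻¹), applied to pixels with canopy
height of at least 4 m; carbon density is $AGCD = 0.47\,AGBD$. The height
floor applies to *biomass* only: height summaries keep sub-threshold
pixels, which is why a summary table can show a height minimum of 0 m
alongside a biomass minimum of 12.54 Mg ha⁻¹ (the allometry at exactly
4 m). Quantiles use linear interpolation between order statistics
(R type 7). A published rounding variant of the coefficients
(1.453, 1.555) changes results by < 0.1% and can be supplied through
`allometry_params()`.

## Eddy-covariance post-processing

The half-hourly chain is: `qc_screen()` (drop quality-flag-2 records and
|flux| > 50 µmol m⁻² s⁻¹ — the conventional physical range; screening only
marks records, values stay for audit), `add_storage()` (NEE = turbulent
flux + storage), `ustar_threshold()` / `apply_ustar_filter()`,
`footprint_exclusion()`, `gapfill()`, `partition_nee()`,
`aggregate_flux()`.

* **u\* threshold.** Nighttime (global radiation < 10 W m⁻²) records are
  split by season and into 6 temperature classes; within a class, 20 u\*
  quantile classes. The class threshold is the mean u\* of the lowest
  class whose mean flux reaches 95% of the mean of all higher classes;
  classes with |r(Ta, u\*)| > 0.4 are skipped. Aggregation: median over
  temperature classes, maximum over seasons. A 100-draw bootstrap over
  nights gives the threshold distribution.
* **Footprint.** The two-dimensional flux-footprint parameterisation
  (crosswind-integrated footprint in scaled upwind distance, Gaussian
  crosswind spread, stability through the Monin–Obukhov profile
  correction) is evaluated per record, rotated to the wind direction, and
  averaged. Records outside the validity envelope (zm/L < −15.5,
  u\* ≤ 0.1 m s⁻¹) are skipped and counted. The `r`% source area is the
  smallest cell set containing `r` of the grid total.
* **Gap-filling.** A bagged regression-tree ensemble (random forest,
  100 trees) of NEE on global radiation, air temperature, VPD and cyclic
  encodings of hour-of-day and day-of-year. Cyclic encodings avoid the
  midnight/new-year discontinuities of raw hour and day numbers.
* **Partitioning.** Nighttime NEE is respiration. The Lloyd–Taylor
  temperature sensitivity $E_0$ is fitted in 15-day windows stepped by
  5 days ($T_{ref}$ = 288.15 K, $T_0$ = 227.13 K); the final $E_0$ is the
  median of window estimates with relative SE below 50% — a robust
  aggregate; taking the few lowest-SE windows instead is biased upward
  here because windows with little temperature contrast ride the
  $R_{ref}$–$E_0$ ridge. Reference respiration is re-estimated in 4-day
  windows by closed-form least squares and interpolated. GPP = RECO − NEE,
  zero at night, so the identity NEE = RECO − GPP holds per record.
* **Aggregation.** 1 µmol CO₂ m⁻² s⁻¹ over a half hour is
  1800 × 44.01 × 10⁻⁶ g CO₂ m⁻², and 10⁻² converts g m⁻² to Mg ha⁻¹; a
  sustained 1 µmol m⁻² s⁻¹ over 365 days is therefore 13.879 Mg CO₂ ha⁻¹.
  Periods are half-open 7-day (or 365-day) blocks from the series start,
  so weekly sums reproduce the annual sum exactly.

## Uncertainty budget

Three components, combined as independent variances
(`uncertainty_budget()`):

* **Random error** (`random_error()`): paired flux differences under
  similar meteorology (same time of day, ±5 days, |ΔRg| < 50 W m⁻²,
  |ΔTa| < 2.5 °C, |ΔVPD| < 5 hPa), pooled as SD/√2 in flux-magnitude
  bins. Pooling matters: conditioning on a single record makes its own
  error a constant offset and biases the per-record SD low by √2.
* **u\* filtering and gap-filling** (`bootstrap_uncertainty()`): 100
  iterations each; the u\* component re-draws the threshold from its
  bootstrap distribution, the gap-filling component refits the filler on a
  resample of the training records. The SD across the recalculated
  aggregates gives the component SDs; all recalculated series are retained
  for audit.

For period sums, the random component is computed per diurnal stratum
(night/day) as $\sqrt{\sum_{meas,s} \sigma_i^2}\cdot(n_s/n_{meas,s})$ and
the strata combine in quadrature: filled values are predictions of a model
trained on the measured records of their own regime (night gaps are
predicted from night-like training data), so their mean error follows that
stratum's measured noise rather than varying independently; the scaling is
the closed-form standard deviation of a gap-filled sum under a shared
training sample. With nothing filled it reduces to the plain independent
sum; without it the annual budget demonstrably undercovers. Calibration is checked on twenty seeded year-long
fixtures: the planted annual NEE must fall within ±2 total SDs of the
estimate in at least 90% of replicates.

## Satellite upscaling

GPP is proportional to solar-induced fluorescence with season-specific
slopes fitted through the origin ($\hat\beta = \sum xy/\sum x^2$); seasons
follow the austral month-wise convention (DJF summer, MAM autumn, JJA
winter, SON spring). Respiration is

$$RECO = R_0 \frac{1 + k\,LSWI}{1 + k\,LSWI_{max}}
  \exp\!\left(E_0\left(\frac{1}{T_{ref}-T_0} -
  \frac{1}{LST-T_0}\right)\right),$$

fitted by bounded multi-start Levenberg–Marquardt. **Identifiability:**
the likelihood is exactly flat along the $(R_0, LSWI_{max})$ ridge — only
$R_0(1+k\,LSWI)/(1+k\,LSWI_{max})$ is identified — so $LSWI_{max}$ is
taken as the observed maximum water index (a site property, as in standard
water-scalar respiration models) and only $R_0, k, E_0$ are free;
`fit_lswimax = TRUE` restores the free fit. The functional form lives in a
single constructor (`reco_model()`) so an alternative can be swapped in.

NEE maps are RECO − GPP per cell. Coarse predictor rasters are downscaled
bilinearly, or by predictor-weighted redistribution that conserves the
coarse-cell mean. Validation against tower fluxes removes outlier pairs
with a Hampel filter (rolling median, window 7, 3 scaled MADs — defaults,
since no parameters are standard) on the paired differences, then fits an
origin-constrained regression; R² is computed about the 1:1 line, the
relevant reference when the question is agreement, not linearity.

The spatial extrapolation factor is the ratio of medians of per-pixel
2013–2020 mean NEE over an EFC and over the tower footprint
(`compute_pext()`); it is scale-invariant, equals 1 when the footprint is
a random subsample of the EFC, and carries a 183-day validity window (a
six-month update cycle).

## Registry

`register_property()` counts 30-m cells whose centres fall inside the
property boundary. `accrue()` converts a period's footprint NEE to
property-level net removal, $\sum_{EFC}(-NEE \cdot P_{Ext} \cdot area)$;
positive removals issue whole units (1 unit = 1 Mg CO₂ net removed) by
flooring with a carried residual in [0, 1); emission periods reduce the
running balance but never claw back issued units (conservative choice).
Entries chain by SHA-256 over a canonical sorted-key JSON serialization —
implemented in R and checked against the published test vectors; the
algorithm name is recorded per entry for forward migration. Conservation
(units + residual = cumulative positive removals) and order-sensitive
tamper detection are tested properties.

## Synthetic study conditions

The fixture generators define the conditions every test runs under; all
are seeded and bit-reproducible.

* **Landscape** (`gen_landscape()`): `k` contiguous patches
  (farthest-point-seeded nearest-seed tessellation, which keeps patch
  sizes comparable), Gaussian elevation/height per cluster, per-cluster
  forest fraction.
* **Flux series** (`gen_ec_series()`): nighttime NEE is Lloyd–Taylor
  respiration ($R_{ref}$ = 3 µmol m⁻² s⁻¹, $E_0$ = 200 K), daytime NEE
  subtracts a rectangular-hyperbola light response (α = 0.06,
  $GPP_{max}$ = 10 µmol m⁻² s⁻¹); meteorology is an austral mid-latitude
  annual cycle with persistent synoptic temperature anomalies (AR(1),
  SD 3 °C) and day-scale cloudiness. Nighttime records below
  u\* = 0.30 m s⁻¹ retain 45% of their flux (sharp onset); friction
  velocity is lognormal with calm nights a minority, so screening plus
  the 8% gap rate and 5% flag-2 rate leaves roughly three quarters of the
  record as good-quality data. Gaussian noise SD is 2 µmol m⁻² s⁻¹.
  These settings put the annual NEE at a few Mg CO₂ ha⁻¹ yr⁻¹ of net
  uptake with a total SD near 0.2 — the regime the method is meant for.
* **Satellite series** (`gen_satellite_series()`): 46 8-day periods per
  year (last truncated); GPP proportional to a seasonal SIF cycle with
  10% noise; LST 292 ± 30 K with 6-K pixel offsets; LSWI 0.48 ± 0.35
  capped at 0.87; RECO from the adopted form with residual SD
  2.8 g C m⁻² day⁻¹. The dynamic ranges were chosen analytically so the
  respiration signal variance is consistent with the fit quality this
  model family attains at that residual scale (R² near 0.5).

What passing tests show — and do not. Parameter recovery on these
fixtures establishes that the estimators are consistent and correctly
implemented under the generating assumptions (Lloyd–Taylor truth,
MCAR-or-block gaps, iid Gaussian noise, sharp u\* onset). Real series
violate these in known ways: heteroscedastic and autocorrelated flux
noise, advection not captured by any u\* filter, gradual turbulence
suppression, decoupled storage, sensor drift. The calibration check bounds
estimator-plus-budget behaviour only under the stated conditions.

## Problem sizes and degenerate inputs

Tests run at reduced but statistically adequate sizes: clustering on
50×50–60×60 grids, silhouette selection on 5 × 400 draws, flux pipelines
on 90–365-day series, RECO fits on up to 25 pixels × 8 years
(n = 9200), calibration on 20 year-long replicates with 100-draw
bootstraps. Degenerate inputs fail loudly: fewer distinct observations
than clusters, all-zero SIF seasons, LST at or below $T_0$, series with
remaining gaps at aggregation, stale extrapolation factors, boundary
polygons outside the map, head-hash mismatches on ledger append.

## Known limitations

* No raster I/O beyond plain-text ASCII grids; no CRS transformations
  (inputs are assumed co-registered, UTM 18S by convention).
* The storage term is consumed, not computed from concentration profiles;
  raw 10-Hz processing is upstream.
* The respiration form is one member of the water-scalar family; the
  constructor isolates it so an alternative can be swapped in.
* Fractional unit issuance, alternative gap-fillers, and
  footprint-weighted (rather than threshold) flux exclusion are not
  implemented.
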