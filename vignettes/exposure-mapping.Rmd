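---
title: "Methods: spatiotemporal RF-EMF exposure mapping with rfemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal RF-EMF exposure mapping with rfemap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rfemap estimates and maps the radiofrequency electromagnetic-field (RF-EMF)
dose absorbed by the population of an urban district, expressed as
whole-body and whole-brain specific absorption rate (SAR, mW/kg) on a
regular 100 x 100 m analysis grid. Three exposure pathways are modelled and
fused: ambient downlink fields from outdoor base stations (far field),
indoor sources (WLAN access points, femtocells, Wi-Fi use, plus the
attenuated outdoor field), and the user's own mobile phone (near field,
uplink). This vignette is the package's account of the underlying models,
the tunable parameters, the numerical choices, and what the bundled
synthetic scenes can and cannot demonstrate.

```{r setup}
library(rfemap)
```

## Outdoor surface: lognormal ordinary kriging

Urban downlink fields measured along a drive test are approximately
lognormal, so interpolation happens on the natural-log scale. The workflow
is:

1. Per-location band levels (five downlink bands in a typical drive test)
   are combined by root-sum-of-squares into a single total field
   (`combine_bands()`); incoherent sources add in power. Per-band kriging
   remains possible by passing a single band's rows instead.
2. `fit_variogram()` estimates the empirical semivariogram of `log E` in 15
   distance bins up to half the largest pairwise distance and fits an
   exponential model (spherical and Gaussian available) by weighted least
   squares.
3. `krige_grid()` solves the ordinary-kriging system at every cell centre
   using only measurements within a local neighborhood of four variogram
   ranges, which amounts to a locally varying mean. Cells with no
   measurement in the neighborhood fall back to the global log mean with
   the total sill as variance and carry a `flagged` column — the map stays
   total, and the flag preserves honesty.
4. The log-scale prediction and kriging variance are back-transformed with
   the lognormal moment formulas,
   `z_lin = exp(z_log + s2_log/2)` and
   `s2_lin = exp(2 z_log + s2_log) (exp(s2_log) - 1)`.

`loo_cv()` implements leave-one-out cross-validation with an optional
exclusion radius around the held-out point, probing how interpolation
quality degrades as the unmeasured area grows.

**Variogram weighting.** The textbook choices for the weighted
least-squares fit are pair counts `N_k` and `N_k / h_k^2`. We default to
`N_k / h_k^2`: in simulation studies on the package's own generator (20
scenes, 1000 points, 300 m true range) pair-count weights let the
long-lag semivariances — which fluctuate strongly in any single finite
realization — dominate the fit and produced both collapsed and runaway
range estimates, while `N_k / h_k^2` recovered the range to within a few
percent on average. The fitted range is also capped at the largest fitted
lag, since no longer range is identifiable from the data.

**Variogram-at-zero convention.** `vg_gamma()` returns 0 at exactly zero
distance and the nugget as the right-limit; the kriging systems therefore
treat coincident points as the same support, making ordinary kriging an
exact interpolator at zero nugget (asserted to 1e-9 in the tests).
Coincident duplicate measurements are averaged in log space before any
fitting to keep the systems non-singular.

## Temporal rescaling: diurnal profiles

Fixed monitoring nodes record the field in three downlink bands around the
clock. To remove long-term level changes, every node-day is normalized:
`eta_i = E_i^2 / Ebar_day^2`. Two readings of the day normalizer are
shipped because the printed form of this normalization is ambiguous:

* `method = "literal"` (default): `Ebar_day` is the arithmetic mean of
  `E`, squared afterwards — the literal reading.
* `method = "rms"`: `Ebar_day^2` is the mean of `E^2`. Under this reading
  the day-average of `eta` is exactly 1, and the profile estimator is an
  unbiased estimate of the generator's configured diurnal curve. The
  literal reading carries an `O(amplitude^2)` positive bias (about 4% at
  the default amplitude), which is why the generator round-trip checks use
  the RMS mode.

`build_profile()` pools normalized values across all nodes and days and
averages within each hour-of-day bin; because each day is normalized by
its own level, nodes with different absolute levels contribute identically
(level cancellation is asserted in the tests). Hours without data are
filled by circular linear interpolation and flagged.

`temporalize_cell()` expands a kriged cell estimate into a time-varying
distribution: `n = 20000` base samples from Normal(`z_lin`, `s2_lin`)
truncated at zero (fields are nonnegative; negative draws are redrawn),
each assigned a uniform hour of day and a band drawn from configurable
band weights (equal thirds by default — the combination weights across
band profiles are not otherwise constrained), the squared sample scaled by
the profile's `eta`, and the square root returned. `fit_best()` then fits
gamma and normal families by maximum likelihood and keeps the family with
the smaller Kolmogorov–Smirnov statistic.

The hour of day is uniform over 24 h — the cell distributions describe
whole-day residential exposure, not coupled to the person-hour time
budgets below.

## Indoor exposure

Three mechanisms combine per building (`indoor_profiles()`), and each
Monte-Carlo sample keeps its source decomposition so contribution
accounting downstream is exact:

* **WLAN + femtocell SAR.** Either calibrated lognormals moment-matched to
  the package's indoor calibration table, or a trained low-rank surrogate
  evaluated at random source/occupant positions. The calibration table's
  whole-body median cell is internally inconsistent in its source (it
  prints below the 25th percentile); only the mean/SD columns are used.
  The table was estimated for a child; applying it to adults is a
  deliberate conservative choice, since child SAR exceeds adult SAR for
  these sources.
* **Wi-Fi use SAR**, sampled independently of occupant position from the
  calibrated per-age, per-tissue lognormals.
* **Penetrated outdoor field.** `penetrate()` applies
  `V_I = V_O 10^(-dB/20)` with a 9.5 dB default, the literature mean for
  the 900 MHz-equivalent band; the attenuated field is converted to SAR by
  `field_to_sar()`. In contribution accounting this component is tagged
  *outdoor*: it is base-station dose that happens to be received indoors,
  and tagging it this way is what lets the outdoor share grow toward the
  upper percentiles where ambient hotspots dominate.

### The low-rank tensor surrogate

`lra_fit()` approximates the SAR response in a room as a finite sum of
rank-one products of univariate functions,
`sum_l b_l prod_i v_l_i(X_i)`, over five inputs: source wall position and
height, occupant x/y, occupant rotation. Univariate functions are
orthonormal Legendre polynomials (default degree 4) on inputs scaled to
`[-1, 1]`. Training is greedy: each rank-one term is fitted to the current
residual by alternating least squares (per-dimension linear solves, sweeps
until the relative training-RMSE change drops below `1e-8` or 100 sweeps),
then the normalizing constants `b` are re-estimated jointly. A final
CP-style refinement re-solves each dimension across all ranks jointly;
without it, greedy deflation alone cannot recover even exactly
representable rank-2 targets beyond ~1e-3 relative error, while with it
machine precision is reached. The exact-recovery tests raise the sweep cap
to 1000 and drop the tolerance — deep-convergence settings for a
noiseless target; the statistical defaults are the spec above.

The training ground truth (`sar_oracle()`) is an analytic stand-in for
full-wave dosimetry: inverse-square in the 3D source-to-torso distance
with a near-field clamp at 0.3 m and a smooth posture modulation
`1 + 0.3 cos(rotation)`. The source is mounted near the ceiling
(2.0–2.5 m), the usual installation height for access points, and the
occupant torso centre sits at 1.0 m, so the minimum source–torso distance
stays near 1 m. This matters for interpretability of the surrogate tests:
with a free-height source the inverse-square law approaches its
singularity inside the domain and no low-order separable expansion can
follow it; with the realistic mount the rank-5, degree-4 surrogate reaches
a held-out relative RMS error of a few percent at 500 training points.

### The PCA + kriging 2D surrogate

For a Wi-Fi source at an unknown apartment position,
`pca_kriging_fit()` represents training field maps (one per known source
position) by a linear-kernel PCA, keeps the smallest number of components
reaching the explained-variance threshold (default 99.5%), krige's each
component score over source-position space with a zero-nugget exponential
model (range: half the largest source-to-source distance), and
reconstructs maps by inverse PCA. Zero nugget makes training maps
reproduce exactly; negative reconstructed pixels are clipped to zero and
counted.

## Uplink dose model

`uplink_sar()` evaluates the daily time-averaged dose

```
E_tel = 0.25 p3G / 86400 * t * SAR_v * p_v * Pv
      + 0.25 / 86400 * p3G * V_d * SAR_d * p_d * Pd / T
```

exactly as printed in its source, including the 0.25 prefactor in both
terms and the appearance of `p3G` in the data term; the prefactor's
physical meaning is not documented anywhere we know of, so a
`include_quarter_factor = FALSE` escape hatch exists for sensitivity
analysis. The model is homogeneous of degree 1 in `t`, `V_d` and the
powers, of degree −1 in the connection speed, and term-additive — all
asserted exactly in the tests.

In the calibrated Monte-Carlo mode (`uplink_profiles()`), the joint spread
of usage and transfer-function parameters is collapsed into one shared
lognormal intensity factor multiplying the deterministic dose. Because a
product of lognormals is lognormal, this closure lets the reference SAR be
solved so that the sample median and mean match the mobile-phone
calibration table exactly (median = deterministic dose, mean/median ratio
fixes the sdlog). Behavioural usage is identical across population groups;
only age-specific transfer functions differ. Laterality and posture enter
only through the collapsed spread, as no quantitative treatment is
available.

## Population geoprocessing

`classify_buildings()` maps declared use to residential/office/mixed
(mixed splits floor area by declared share; unknown codes default to
residential with a warning — conservative for residential exposure).
`allocate_population()` implements surface-ratio allocation: building *i*
receives `sum_j (S_ij / S_j) P_j` over intersecting zones *j*, per age
class (children under 15, adults 15 and over), with slivers below 0.5 m2
dropped; the occupational population (15–64) is allocated from the
district aggregate proportionally to office areas. When zones' housing
areas are fully covered by buildings, allocation conserves populations
exactly (asserted in the tests).

Default time budgets (`time_budget()`): residents spend 21.5 h at home and
2.5 h outdoors; workers 16 h at home, 6 h in the office, 2 h outdoors.
Each group's budget must sum to 24 h. Home and office shares put roughly
90% of the day indoors, consistent with the time-activity surveys this
kind of assessment relies on. The worker group's home hours are *not*
localized inside the district: workers' residences are represented by the
residential groups (or lie outside the district), so localizing them would
double-count. Values are configuration, not constants.

## Aggregation

`field_to_sar()` converts field strength to dose via the plane-wave power
density `S = E^2 / 377` and a downlink transfer function in
(mW/kg)/(W/m2). The uplink transfer functions are solved by the
calibration above; the downlink entries are documented placeholders
(whole body 100, whole brain 80) chosen so that ambient downlink dose at
typical urban field strengths (0.5–0.7 V/m) sits about an order of
magnitude below the indoor-source dose — reproducing the observed source
ranking (indoor first, outdoor second, mobile under a few percent) —
because the reference conversion tool's internals are not published.
Absolute downlink dosimetry should be treated as configuration.

`aggregate_cell()` fuses components per tissue: the total sample budget
(20,000 per cell, matching the per-cell distribution size used upstream)
is apportioned across components *proportionally* to person-hours rather
than using person-hours as absolute counts — this bounds cost while
preserving the weights. Every sample receives an age-matched uplink draw
on top (phone dose is cumulative with ambient dose). Summaries are 20
percentiles (vigintiles P5…P100, plus P99 because upper-tail results are
conventionally quoted at the 99th), mean, SD, and value-weighted source
shares per percentile bin. Percentiles use linear interpolation between
order statistics (type 7) for determinism. District-wide curves
(`contribution_curves()`) pool samples across cells weighted by cell
person-hours; pooling (rather than averaging per-cell percentiles) is the
default interpretation, and the per-cell shares remain available for the
alternative.

Cells with zero person-hours are flagged empty and become no-data in the
maps. Maps are written as plain-text artifacts: per-tissue CSV percentile
tables and a GeoJSON FeatureCollection of grid-cell polygons carrying
P50/mean/SD properties (`write_maps()`). Coordinates are a local planar
metric frame throughout — the analysis is grid-based and needs no geodesy.

## The synthetic scene

`simulate_scene()` generates every input the pipeline needs, so all stages
are testable without external data:

* **District**: a recursive binary partition of the extent into census
  zones (exact tiling, so population conservation is testable exactly),
  buildings as axis-aligned rectangles with floors, declared use and
  derived housing/office areas; zone housing areas are the sums over
  member buildings, and integer populations are spread by largest
  remainder (exact totals). Defaults emulate a dense inner city:
  24,000 residents/km2, 14% children.
* **Drive test**: locations scattered along random straight pseudo-street
  segments (reproducing survey clustering, which is what makes
  local-neighborhood kriging meaningful); the log-field is a Gaussian
  random field with exponential covariance (median 0.6 V/m, log-variance
  0.35, range 300 m) plus two hotspot bumps, simulated exactly by dense
  Cholesky factorization (documented cutoff 5000 points — desk scale).
  Five band levels per location under fixed power shares, RSS-consistent
  with the total.
* **Sensor series**: per node, `E = level * sqrt(shape(hour)) * noise`
  with lognormal node levels, configured cosine diurnal curves
  (hour-mean exactly 1) and multiplicative lognormal noise.
* **Indoor training sets**: Latin-hypercube designs over the room's
  5-dimensional input space, evaluated by the analytic SAR ground truth.

Everything is driven by one run-level seed (per-stage sub-seeds are
derived deterministically), and a fixed seed makes all artifacts —
including written map files — byte-identical, which the acceptance checks
assert.

**What passing tests do and do not show.** The generator reproduces the
statistical *structure* assumed by the methods: lognormal spatially
correlated fields, multiplicative diurnal modulation, separable-ish smooth
indoor dose surfaces, census-consistent geometry. Real drive tests add
measurement noise floors, anisotropy along street canyons, temporally
correlated network load, non-rectangular parcels and mobility — none of
which are emulated. Green tests therefore validate the estimators against
their own assumptions and the pipeline's plumbing end to end; they do not
validate the assumptions against a real city.

## Problem sizes

The bundled checks use 10 x 10-cell scenes with 400 drive-test points for
end-to-end runs, 1000-point scenes (20 replicates) for variogram recovery,
36 nodes x 30 days for profile round trips, 500/200 training/held-out
points for the surrogate, 20,000 samples per cell distribution, and a
1e6-draw Monte-Carlo oracle for the back-transform — sizes at which every
estimator's error is far from its asymptotic floor yet each check runs in
seconds to a couple of minutes on a single core.

## Known limitations

* No kriging with external drift, co-kriging, or anisotropy; no seasonal
  or annual trend modelling (deliberately normalized away).
* No 2G/4G/5G uplink technologies; no per-band uplink power control.
* No commuting/mobility model: outdoor person-hours derive from the
  resident and worker populations of each cell's buildings, which likely
  understates outdoor exposure in transit-heavy areas.
* Whole-brain values in surrogate mode are scaled from the whole-body
  surrogate by the calibration-table tissue ratio rather than trained
  separately.
* No inter-apartment source leakage; penetration loss is a single
  deterministic value, not material-dependent.
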