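---
title: "Multi-resolution NDVI fusion for row crops: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution NDVI fusion for row crops: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vinefuse)
```

## The problem

Decametric satellite imagery (Sentinel-2-class, 10 m pixels) is free and
frequent, but in a vineyard a 10 m pixel mixes vine canopy with the bare or
grassed inter-row ground. With rows 2 m apart and canopy strips roughly 1 m
wide, about half of every satellite footprint is soil, so satellite NDVI is a
blend that systematically understates canopy vigour and tracks the inter-row
state as much as the vines. Centimetric UAV imagery (5 cm ground sampling
distance) resolves individual canopy pixels but covers less area, less often.

`vinefuse` fuses the two: it matches each UAV pixel centre to the satellite
footprint that contains it, and then aggregates per-pixel UAV NDVI three ways
per satellite cell — over the entire cell, over canopy pixels only, and over
inter-row pixels only. The canopy-restricted aggregate is a vigour estimate at
satellite-cell resolution that is free of soil mixing; the inter-row aggregate
isolates the ground signal. Around this core the package provides canopy
segmentation, ordinary-kriging fusion of soil moisture against point sensors,
threshold-based attention points, and a genetic-algorithm route planner —
plus a synthetic vineyard simulator so that every stage is testable without
field data.

## The index and its decomposition

NDVI per pixel is $(\rho_{NIR}-\rho_{R})/(\rho_{NIR}+\rho_{R})$. Pixels with
$\rho_{NIR}+\rho_{R}=0$ are undefined and become nodata rather than zero: a
zero would masquerade as moderate vigour. Because the index is a ratio it is
invariant to a common positive scaling of both bands, so it may be computed on
reflectance or on raw digital numbers — but not on a stack that mixes the two
radiometries, which the raster container rejects at construction.

A UAV pixel belongs to satellite cell $(i,j)$ iff its centre lies in the
half-open footprint box (west edge inclusive, east exclusive; north inclusive,
south exclusive). Half-open boxes tile the plane, so each centre is assigned
to exactly one cell — with a 10 m / 5 cm pixel ratio every interior cell
receives exactly $200 \times 200 = 40\,000$ centres. Membership is a
point-in-box test on the centre, not an area intersection; sub-pixel area
weighting is deliberately out of scope.

Per cell, the canopy ($P_{vin}$) and inter-row ($P_{int}$) aggregates sum
per-pixel NDVI over the restricted set. Two denominator conventions are
offered:

* **restricted** (default): divide by the size of the restricted set — a true
  mean of the selected pixels, which is what "canopy vigour" means
  scientifically. It obeys the exact reconstruction identity
  $\mathrm{NDVI}_{uav} = (|P_{vin}|\,\mathrm{NDVI}_{vin} +
  |P_{int}|\,\mathrm{NDVI}_{int}) / |P|$.
* **printed**: divide by the full cell cardinality $|P|$ regardless of the
  restriction. Then the three maps satisfy the exact additivity
  $\mathrm{NDVI}_{uav} = \mathrm{NDVI}_{vin} + \mathrm{NDVI}_{int}$ per cell.

Both identities hold to machine precision and both are asserted in the test
suite over random masks. Cells whose UAV coverage falls below 95% (the
configurable `min_coverage`) are nodata, restricting maps to fully covered
footprints.

Note one subtlety the test suite also pins down: aggregating per-pixel ratios
(the whole-cell UAV aggregate) is *not* the same number as the ratio of
area-averaged reflectances (what a real decametric sensor measures). On a
mixed canopy/soil scene the two differ visibly; the package computes both so
the difference is observable rather than hidden.

## The synthetic scene

The simulator lays out parallel canopy strips of configurable width and
spacing (defaults 1 m and 2 m — the surveyed geometry, leaving a 1 m bare
gap), at any azimuth, on a metric local grid converted to WGS84 degrees with
the metres-per-degree scale factors at the scene latitude. Ground truth is
generated at 5 cm resolution by default and rendered to any coarser GSD by
exact block averaging of reflectance, so a 10 m "satellite" pixel mixes
canopy and soil exactly as a convex combination in reflectance space.

The reflectance model is linear in a latent vigour $v \in (0,1]$: canopy
$\rho_R = 0.18 - 0.12v$, $\rho_{NIR} = 0.25 + 0.55v$; soil $\rho_R = 0.22$,
$\rho_{NIR} = 0.30$. These values make canopy NDVI span roughly 0.3–0.85 and
put soil near 0.15, the typical vine/soil contrast in multispectral surveys;
`vigour_for_canopy_ndvi()` inverts the model when a scene with a prescribed
canopy NDVI is wanted. Vigour varies as base + linear gradient + a smooth
random field of amplitude `vigour_noise_sd` (default 0.05); independent
Gaussian reflectance noise (`noise_sd`, default 0.01) is added per
ground-truth pixel. The soil-moisture field is a Gaussian random field with a
configurable correlation length (default 15 m), scaled to 0.22 ± 0.08 VWC and
clipped to the capacitance-sensor calibration range [0, 0.57] m³/m³, which
the sensor-table reader also enforces on input. Smooth fields are synthesised
by FFT convolution of white noise with a Gaussian kernel (circular boundary —
harmless for synthetic truth and cheap at any correlation length).

What the simulator does *not* emulate: radiative transfer and shadowing,
phenological dynamics across survey dates, georeferencing error between the
two platforms, weeds or cover crops in the inter-rows, and atmospheric or
radiometric calibration artefacts. Tests passing on these scenes therefore
demonstrate the correctness of the algorithms under ideal geometry and
radiometry, not robustness to the full messiness of field acquisitions.

## Canopy segmentation and row orientation

The canopy/inter-row partition that the decomposition needs is produced by
NDVI thresholding: Otsu's between-class-variance maximiser on a 256-bin
histogram by default, or a fixed threshold (pixels with NDVI ≥ threshold are
canopy). Morphological opening with a disc of radius 2 pixels and removal of
connected components below 0.1 m² (both configurable) suppress the speckle
that 5 cm imagery produces. The inter-row mask is the complement over valid
pixels, so disjointness and completeness hold by construction. Thresholding
was chosen over supervised classification or geometric row fitting because
canopy and soil are strongly separable in NDVI and it needs no training data;
object-based analysis is a documented non-goal.

Row azimuth is estimated by projecting pixel centres onto the axis
perpendicular to each candidate direction (0–180° in 0.5° steps, then local
refinement) and maximising the variance of the binned 1-D NDVI profile: rows
stack into alternating high/low bins only at the true azimuth. Structure is
declared absent when the best profile variance is below 1.2× (configurable)
the same statistic computed on spatially shuffled values — a permutation null
that makes the ratio ≈ 1 on structureless maps regardless of bin occupancy.

## Soil-moisture fusion by kriging

Soil moisture is estimated at covariate points through a linear link
(intercept + coefficients × covariates, clipped to [0, 0.57] VWC) and
interpolated by **ordinary kriging**: semivariance-based weights solving the
augmented system with a Lagrange multiplier enforcing $\sum w_i = 1$ (no
stated mean, hence ordinary rather than simple kriging). Distances are
computed on a local metric projection (degrees scaled by the
metres-per-degree factors at the mean latitude) because degrees are
anisotropic in metres. Exponential, spherical and Gaussian variogram families
are available, parameterised by nugget, partial sill and effective range (the
exponential and Gaussian use the conventional factor-3 effective range).
$\gamma(0)=0$ on the diagonal, so with zero nugget kriging interpolates the
samples exactly.

Variogram fitting is weighted least squares of the chosen family to the
empirical semivariogram (15 lag bins up to half the maximum pairwise
distance), with weights $N_h/h^2$ so that the shape-carrying short lags
dominate. From a single realisation the nugget/partial-sill split is weakly
identified; the recoverable quantities are the range and the plateau
(nugget + sill), which is what the recovery tests assert.

Calibration against in-situ sensors is an exhaustive grid search over
variogram parameters × link coefficients, minimising the mean absolute error
between kriged estimates at the sensor locations and the measured values;
ties break toward the smaller nugget, then the smaller range. The spatial
extent over which a calibrated configuration remains valid is left to the
user — the package applies it wherever asked.

## Attention points and routing

A management cell is flagged for irrigation when kriged moisture falls below
`moisture_min` and for fertilisation when canopy NDVI falls below
`ndvi_min`; severity is the sum of fractional threshold shortfalls. The
thresholds are deliberately configuration, not constants: sensible values
depend on soil, variety and season (the shipped pipeline defaults are 0.22
VWC and 0.55 NDVI on the synthetic scene).

The visiting route is ordered by a permutation-encoded genetic algorithm:
tournament selection of size 3, order crossover, segment-inversion mutation,
elitism of one, minimising
$w_{dist}\cdot\mathrm{length} + w_{priority}\cdot\sum_k k\cdot s_{(k)}$ —
a scalarisation that trades tour length against visiting severe points early
(default $w_{priority}=0$: pure shortest tour). Segment inversion (the
2-opt move) was chosen over a plain element swap after it proved markedly
more reliable at reaching the exhaustive optimum on 8-point instances; with
it, the default GA (population 100, 300 generations) matches brute force on
every tested instance. Elitism makes the best objective non-increasing across
generations, which is asserted as an invariant. Routes are deterministic
given the seed and close back at the depot; an option exists to snap legs to
row axes when a partition is supplied.

## Numerical and I/O conventions

* Coordinates are WGS84 degrees throughout; grids are row-major, 0-based,
  origin at the upper-left corner, latitude decreasing with row index.
* Rasters are stored as multiband float32 TIFF with a JSON sidecar
  (`<file>.aux.json`) carrying the grid, band map, radiometry and value
  scale/offset; the nodata mask rides as a trailing 0/1 band. Nodata is NA in
  memory. Round-trips are exact to float32 (~2×10⁻¹⁰).
* Class boundaries for vigour classification are half-open: low < t_low ≤
  medium < t_high ≤ high; in "tertiles" mode the thresholds are the
  33.3/66.7 empirical percentiles. Map products use green = high, yellow =
  medium, red = low.
* The pipeline derives per-stage seeds from one global seed
  (seed × 1000 + stage index, mod 2³¹), so partial reruns reproduce full
  runs; the run manifest records config, seeds and MD5 checksums of every
  product, and rerunning an identical config reproduces identical checksums.

## Problem sizes used in the shipped tests

The test-suite and acceptance-script scenes are desk-scale by design: 15–50 m
fields at 5–10 cm ground truth (up to 600×600 ground-truth pixels), 3×3 to
5×5 satellite cells, 200-point variogram fits, 5–20-sample kriging systems
checked against dense solves, and 8-point routes checked against exhaustive
enumeration. These sizes exercise every code path at full fidelity; nothing
in the implementation is specific to them, and the same functions run on
arbitrarily larger rasters.

## Known limitations

* Footprint membership is centre-point, not area-weighted; cells at the UAV
  coverage boundary are masked rather than partially weighted.
* The kriging module is isotropic and purely spatial (no co-kriging, no
  space-time models); covariates enter only through the linear link.
* Segmentation assumes canopy/soil NDVI bimodality; dense cover crops between
  rows would break the contrast and demand a different feature.
* The local equirectangular metric projection is accurate at field scale
  (tens to hundreds of metres) and mid latitudes; it is not meant for scenes
  spanning degrees.
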