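---
title: "Light-use-efficiency modelling of grassland NPP: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-use-efficiency modelling of grassland NPP: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassnpp)
```

## The model

`grassnpp` implements a production-efficiency (CASA-family) model: monthly
net primary productivity is the product of absorbed photosynthetically
active radiation and a light use efficiency,

$$\mathrm{NPP}(x,t) = \mathrm{APAR}(x,t)\times \mathrm{LUE}(x,t),$$

with $\mathrm{APAR} = \mathrm{SOL}\times\mathrm{FPAR}\times 0.5$ (half of
the incoming shortwave flux lies in the 0.4–0.7 µm band usable for
photosynthesis) and

$$\mathrm{LUE} = T_{\varepsilon 1}\,T_{\varepsilon 2}\,W_\varepsilon\,
\varepsilon_{\max},\qquad \varepsilon_{\max} = 0.604\ \mathrm{g\,MJ^{-1}}.$$

The temperature scalars are anchored to the optimal temperature
$T_{opt}(x)$, defined as the mean air temperature of the month of maximal
greenness at each cell. $T_{\varepsilon 1}$ is a downward parabola equal to
1 at 20 °C and 0.8 at 0 and 40 °C, expressing that ecosystems acclimated to
very cold or very hot optima fix carbon less efficiently.
$T_{\varepsilon 2}$ is a double logistic in the departure of the month's
temperature from $T_{opt}$, falling off faster on the cold side (rate 0.3
per °C) than on the warm side (0.2 per °C) and normalised by 1.1814.
Moisture stress enters through the atmospheric vapor-pressure deficit $D$:
saturation vapor pressure at the land-surface temperature minus that at the
dew point, with the dew point obtained by inverting a regression of
log-precipitable-water on dew point, $\ln U = 1.8084 + 0.0735\,T_d$. Then
$W_\varepsilon = 1.2 e^{-0.35 D} - 0.2$.

### Assumptions and interpretation choices

Several points are under-determined by the published formulation; the
package resolves them as follows and treats each as a fixed design choice:

* **Greenness proxy for $T_{opt}$.** The optimum is defined by the month of
  peak greenness. The input set carries FPAR rather than NDVI, and both are
  monotone canopy-density measures, so the month of maximal FPAR is used.
  Ties go to the earliest month, which keeps the result deterministic.
* **Units in the dew-point regression.** $T_d$ must be in °C there —
  reading it in Kelvin yields astronomically large precipitable water —
  and is converted to Kelvin by adding 273 before the deficit formula,
  which uses the printed offset 273 (not 273.15) throughout. The offset is
  configurable in `casa_params()`.
* **Clamps.** $W_\varepsilon$ turns negative for $D \gtrsim 5.1$ kPa; it is
  clamped at `we_floor = 0` so efficiency and productivity stay
  non-negative, and each clamp activation is reported via a warning.
  $T_{\varepsilon 1}$ is *not* clamped: the published form is the bare
  polynomial, so negative values at extreme optima are possible and are
  flagged rather than hidden.
* **Peak of $T_{\varepsilon 2}$.** With the printed rate constants the
  true maximum of the double logistic sits about 1.1 °C warm of $T_{opt}$,
  and the value at $T = T_{opt}$ (0.9912) is within 0.6 % of that maximum.
  The constants are implemented exactly as printed; verbal characterisations
  of the curve (unit peak at $T_{opt}$, half-value at +10/−13 °C) are
  treated as approximate descriptions.
* **$\varepsilon_{\max}$ units.** NPP is reported in gC m⁻², so 0.604 g/MJ
  is read as grams of carbon per megajoule.
* **Overflow.** The logistic exponents are allowed to saturate: `exp` of a
  large argument becomes `Inf`, the factor $1/(1+\infty)$ becomes 0, and no
  numeric fault occurs even at absurd temperatures.
* **Nodata.** Masks are unioned along the chain — a cell-month masked in
  any input is masked in every product derived from it. The annual layer
  sums the unmasked months of a cell and is masked only when all twelve are.

## Preprocessing

**Compositing.** Satellite FPAR and surface-temperature products arrive as
8-day composites (the final period of a year is shorter). Monthly layers
are day-overlap-weighted means: a period contributes its layer weighted by
the number of its days falling inside the month, which is unbiased at month
boundaries, unlike assigning each composite to its start month. Cells
masked in a period simply drop out of that period's contribution.

**Gap-filling.** Missing cell-months are filled with a natural cubic spline
along the month axis, per cell. Observed values are never modified, and a
spline through collinear points reproduces the line exactly, which the
tests exploit. Outside the observed range the fill clamps to the nearest
observation instead of extrapolating — cubic extrapolation on seasonal data
diverges. Cells with fewer than two observations are left masked.

**Station temperatures.** Air temperature grids come from sparse stations
(41 by default) whose dominant structure in mountain terrain is the
elevation lapse. The interpolator therefore (1) fits
$T = a + b\,\mathrm{elev}$ by least squares, and (2) spreads the residuals
over lon/lat with a thin-plate regression spline (`mgcv::gam`, basis
dimension `min(n_stations − 1, 30)`), adding back $a + b\,\mathrm{DEM}$.
This decomposition was chosen over a single 3-D spline because it is
directly testable by parameter recovery: noise-free stations on a pure
lapse field return the field to machine precision and the lapse rate
exactly, and the fitted $b$ is reported for every month. If all station
elevations coincide the lapse fit is degenerate and the spatial spline
alone is used, with a warning. Stations and grids must already share a
geographic CRS; there is no on-the-fly reprojection.

## Validation

Surveyed dry yield measures aboveground biomass only, while modelled NPP
includes roots. The conversion is
$X_2 = \mathrm{yield}\times 0.45\times(1+R)$: 0.45 gC per g dry matter, and
the root:shoot ratio $R$ (belowground/aboveground; mountain meadow 6.23,
alpine meadow and alpine shrub meadow 7.92) supplying the belowground
allocation — alpine meadows are strongly root-dominated, hence totals are
multiples of the aboveground carbon. Each point is paired with the NPP of
the raster cell nearest its coordinates (nearest-cell, not bilinear: NPP is
a cell aggregate). The report gives, per grassland type and pooled,

$$\mathrm{Error} = \frac{1}{N}\sum \frac{|X_1 - X_2|}{X_2}\times 100\%,
\qquad \mathrm{Precision} = 100\% - \mathrm{Error},$$

so precision + error is exactly 100 in every row, the statistic is
invariant to rescaling both sides, and the pooled error is the
point-count-weighted mean of the group errors. Points with $X_2 = 0$ cannot
enter the relative error and are excluded with a warning; whether the
annual total or a single month's NPP is paired is selectable (`period`),
with annual the default since clipped yields integrate the growing season.

## Partition statistics

Zonal summaries (per elevation band, grassland type or region) report
area, area share, mean, maximum, total and total share. Cell areas come
from the spherical formula
$R^2\,\Delta\lambda\,(\sin\varphi_{top}-\sin\varphi_{bottom})$ with
$R = 6371.0088$ km, so means are area-weighted by default (a simple-mean
flag exists; tables of per-m² averages in the literature rarely state which
is used). Totals convert as gC m⁻² × km² × 10⁻⁶ = TgC. Elevation bands are
half-open $[lo, hi)$ — a cell at exactly 4000 m falls in 4000–5000 — with
default breaks at 1000/2000/3000/4000/5000 m. By construction area and
total shares each sum to 100 % and class totals sum to the global total;
nested partitions aggregate consistently. Monthly series are area-weighted
totals and means over an optional mask, supporting the convention of
reporting radiation absorption over a whole region but efficiency and
productivity over the grassland mask only.

## The synthetic scene generator

Real inputs for this kind of study (MODIS-derived FPAR/LST/precipitable
water, interpolated radiation, a provincial survey) are not redistributable,
so the package generates internally consistent scenes with known truth. The
defaults sketch a high-mountain grassland: a 64 × 64 grid over 4° × 4°,
elevations 2500–4500 m from a smooth random surface, air temperature = a
summer-peaking seasonal cycle + a −6.5 °C/km lapse over the DEM + a ±2 °C
smooth anomaly, land-surface temperature 2 K above air temperature,
precipitable water generated *forward* through the dew-point regression
from a dew point 5 °C below air temperature (so the deficit is always
defined and the regression round-trips to machine precision), FPAR a
Gaussian seasonal bell peaking in August scaled per grassland type, and
monthly radiation of 240–600 MJ m⁻² — all magnitudes a field scientist
would accept for subalpine Asia. Grassland types are elevation terciles
(mountain meadow low, alpine shrub meadow mid, alpine meadow high), and
survey points default to the classic 100/30/20 split over 150 points.

Ground truth is computed by `oracle_casa()`, a deliberately naive per-cell
scalar loop kept separate from the vectorised grid code, so "pipeline
matches truth" is a genuine dual-route check rather than a tautology.
Station noise is Gaussian (°C) and yield noise lognormal multiplicative —
the simplest laws with controllable expected relative error; for yield
noise $e^{\sigma Z}$ the expected validation error is
$E|e^{\sigma Z}-1|$, which the tests compute by quadrature and compare with
the Monte-Carlo pooled error. All randomness flows from the single scene
seed; identical seeds give bit-identical scenes.

What the generator does **not** emulate: orbital and cloud gap geometry,
quality flags, realistic topography or land-cover fragmentation, spatially
correlated observation error, and any disagreement between the model family
and reality. Passing tests therefore demonstrate numerical and structural
correctness of the implementation — not that the model reproduces real
grassland carbon fluxes; with real data, precision near 70–75 % rather than
100 % is the realistic outcome.

## Numerical choices and problem sizes

Tolerances: grid-versus-oracle agreement is asserted at 10⁻⁹ relative
(observed ~10⁻¹⁵); conservation identities at 10⁻⁹–10⁻¹²; lapse-rate
recovery within 5 %; Monte-Carlo calibration of the validation statistic
within five standard errors of the quadrature expectation. Test and
acceptance runs use 64 × 64 scenes for end-to-end checks, ≤ 8 × 8 grids for
brute-force oracle comparisons, 10 replicates × 3 noise levels for the
interpolation degradation study and 50 replicates × 150 points for the
error calibration — sizes at which every statistical assertion is stable
from run to run while the whole suite stays fast.

Raster exchange uses plain-text ESRI ASCII grids (one file per monthly
band, a JSON sidecar for units/CRS/legend) and tables use CSV; values
round-trip through disk exactly at double precision. The ASCII format
carries a single cell size, so grids must have square cells — true of all
scenes the package generates.

## Known limitations

* No soil-moisture submodel: moisture stress is entirely VPD-driven.
* No GPP/autotrophic-respiration split; the model outputs NPP directly.
* Nearest-cell extraction ignores sub-cell heterogeneity at survey points.
* The temporal spline fills gaps per cell; no spatial infilling is done.
* `Tε1` can go negative for optima beyond ~57 °C (reported, not clamped).
* Geographic CRS only; projected grids must be converted upstream.
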