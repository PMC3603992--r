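---
title: "Isobioclimate classification and change analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isobioclimate classification and change analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoclim)
library(dplyr)
```

## The model

isoclim implements a bioclimatic classification workflow for gridded
30-year monthly climate normals (monthly minimum and maximum temperature in
°C and precipitation in mm). Three indices are computed per grid cell from
the monthly mean temperature $t_m = (t^{min}_m + t^{max}_m)/2$:

* **Continentality** $I_c = T_{max} - T_{min}$, the difference between the
  warmest- and coldest-month mean temperatures (°C). Low values indicate
  maritime-buffered climates.
* **Ombrotype** $I_o = P_p / T_p^{(°C)}$, the ratio of yearly *positive*
  precipitation (summed over months with $t_m > 0$ °C) to the yearly
  positive temperature sum. We store $T_p$ in tenths of a degree — the
  scale on which the published thermotype thresholds (1200–2650) are
  expressed — and fold the factor of ten into $I_o = 10\,P_p/T_p$, so both
  indices land directly on their published category scales. A built-in
  consistency test verifies the two conventions agree.
* **Thermicity** $I_t = (T + m + M) \times 10$ with $T$ the annual mean of
  monthly means and $m$, $M$ the coldest month's mean minimum and maximum.
  Under high continentality a compensated index is used:
  $I_{tc} = I_t$ for $I_c \le 18$, $I_t + 5$ for $18 < I_c \le 21$, and
  $I_t + (I_c - 21) + 15$ beyond — continuous at $I_c = 21$ and never below
  $I_t$. Where $I_c > 21$ or $I_{tc} < 120$ the thermotype is classified on
  the positive temperature index $T_p$ instead.

Each index is segmented by a packaged category table (7 continentality,
11 ombrotype, 7 thermotype classes); the three numeric class codes combine
into one integer *isobioclimate* code, $io \times 100 + ic \times 10 + tmo$
(e.g. lower humid 12 / euoceanic 5 / upper mesomediterranean 2 → 1252).
The Mediterranean macrobioclimate is diagnosed per cell by summer drought:
a four-month summer ombrothermic index $I_{os4} < 2$.

Change between a baseline and a projected climatology is counted in
categories per index (a cell moving two continentality classes gets a
continentality change of 2), summed into a total-change map, and summarised
as an area-weighted transition matrix. Across a baseline and two
projections, the unique codes partition into seven disjoint sets (shared by
all, baseline + one projection, disappearing, novel in one, novel in both);
each code also maps to an (io, ic, tmo) coordinate in a 3-D climate cube
with per-period areas.

## Conventions chosen where the source material is ambiguous

These were genuinely open choices; each is a configuration key with the
default stated here.

* **Interval closure.** Printed class bounds such as "13.01–17" are
  two-decimal renderings of a continuous partition. We classify with
  half-open intervals (previous upper, upper], so 13.005 is classifiable
  and a value exactly on a printed upper bound stays in the lower class.
  Out-of-range values are clamped to the extreme classes and flagged
  (policy `extend`), or returned as NA (policy `flag`).
* **Compensation at $I_c = 18$ exactly.** The printed piecewise rule leaves
  18.0 unassigned; we close the gap downward (no compensation at exactly
  18).
* **$T_p$-route trigger.** Both "$I_c > 21$" and "$I_c \ge 21$" circulate
  for the positive-temperature fallback; the default is the strict
  inequality, with the comparator configurable
  (`classify_thermotype(tp_trigger_cmp=)`).
* **Summer windows.** $I_{os2}$ uses July–August (the warmest summer
  bimonth), $I_{os4}$ May–August; both month sets are arguments.
* **Fixed extreme months.** July/January are the default warmest/coldest
  months, appropriate for the California coastal setting the workflow is
  built around; `extreme_months(mode = "data_driven")` detects them from
  the domain-mean cycle instead (ties break to the lowest month number).
* **Ordinal change distance** uses the numeric class codes, so ombrotype
  distances live on the 5–15 scale — consistent with counting "classes of
  change".
* **Patches are code classes.** A "patch" is the set of all cells sharing
  an isobioclimate code, not a contiguous region.
* **Areas are always derived from the grid geometry** (cell size squared),
  never stored or hard-coded.

## Downscaling

`gids_interpolate()` implements gradient-plus-inverse-distance-squared
interpolation: for each target cell and month a least-squares fit
$Z \sim a + C_x X + C_y Y + C_e E$ over the `n_neighbors` nearest coarse
centres, then
$\hat Z = \sum_i w_i \left( Z_i + (X - X_i) C_x + (Y - Y_i) C_y + (E - E_i) C_e \right) / \sum_i w_i$
with $w_i = 1/d_i^2$. A target coinciding with a coarse centre returns that
centre's value. The method reproduces any field affine in $(X, Y, E)$
exactly, which the test-suite exploits as an oracle. The neighbourhood size
is not prescribed by the method's sources; the default of 8 balances
locality against regression stability and is configurable. Rank-deficient
neighbourhoods (e.g. constant elevation) fall back to gradient-free
inverse-distance-squared weighting with a warning, or abort under
`singular_fallback = "error"`. Precipitation is floored at zero after every
step; temperature is never floored.

`bias_correct()` fits, per cell and variable, the linear transform
$z \mapsto \mu_{ref} + (z - \mu_{mod})\,\sigma_{ref}/\sigma_{mod}$ with
moments taken across the twelve monthly normals, falling back to a pure
mean shift when $\sigma_{mod} = 0$. The package operates directly on
monthly normals rather than on the underlying monthly time series, so the
annual cycle plays the role of the sample; the corrected cycle matches the
reference mean and SD exactly, the transform is returned for reuse on a
future climatology, and correcting an already-corrected climatology is a
no-op. `downscale_pipeline()` chains GIDS to an intermediate grid, bias
correction against the reference there, and GIDS to the fine grid.

## Ordination

`cca_bioclim()` implements canonical correspondence analysis directly: the
chi-square-standardised residual matrix
$\bar Q = D_r^{-1/2} (P - r c^\top) D_c^{-1/2}$ is projected by weighted
least squares onto the row-weight-standardised environment matrix, and the
SVD of the projection gives eigenvalues (squared singular values),
canonical coefficients, species scores, and both weighted-average and
linear-combination site scores. Eigenvalue signs are arbitrary in any
eigenanalysis, so each axis is oriented deterministically: the
largest-magnitude species score on the axis is made positive. Plots are
weighted by abundance row totals (each isobioclimate is one plot), not by
patch area, and rare types are not downweighted. Constrained eigenvalues
are verified in the tests to sit below the corresponding unconstrained
correspondence-analysis eigenvalues and to agree with an independent
implementation (vegan). Coefficients are reported both for standardised
variables and per original unit (`coefficients_raw`); the latter scale
inversely when a variable is rescaled, while eigenvalues and species scores
are invariant.

Abundance is percent cover: for each isobioclimate, 100 × (cells of a
vegetation type in the patch) / (total patch cells), so rows sum to 100
minus the share of types excluded by the removal filter. The filter drops
types tagged anthropogenic (urban, agriculture), hydrologic (riparian,
wetland) or unknown, retaining the natural upland types; the packaged
42-type legend is a synthetic stand-in built to this structure (23 natural
types kept).

## The synthetic generator

Real inputs at the intended scale (multi-decade gridded normals, a
downscaled projection, a state vegetation layer) are external data
products, so the package carries a generator that reproduces the
*statistical structure* the analysis assumes, making every stage testable
offline:

* terrain: a bounded sum of random cosine waves (smooth, seeded,
  elevations within ±`relief_amplitude`), with distance from the west edge
  standing in for distance to the coast;
* temperature: a sea-level seasonal cycle (default mean 13 °C, range 8 °C,
  July warmest) whose annual amplitude grows with coast distance,
  saturating at `annual_range_inland` (default 20 °C) with an e-folding of
  25 km — the continentality gradient; a lapse of 6.5 °C/km; a fixed
  10 °C diurnal range;
* precipitation: 700 mm/yr at sea level plus 800 mm/yr per km of elevation
  (orographic), with 90 % falling in the four winter months — a
  Mediterranean regime in which most of the domain passes the
  summer-drought test;
* a future perturbation: uniform warming, precipitation scaling, and a
  continentality boost that widens the July–January range by exactly its
  nominal value;
* vegetation: each cell takes the type with maximal Gaussian suitability
  over (Io, Ic, Itc) plus seeded noise, with type optima spread along the
  moisture gradient so ombrotype is the primary structuring axis.

Noise is independent Gaussian per cell and month, with no spatial
autocorrelation (smoothness comes from the terrain); in the noise-free
limit every downstream index has a closed form in the generator
parameters, which the tests compare against at 10⁻⁹. Northern-hemisphere
seasonality is the default; a hemisphere flag inverts the cycle and is used
to test data-driven month detection.

What passing tests on this generator do **not** show: fidelity to fog
dynamics, storm tracks, coastline geometry, spatially correlated
observation error, or GCM physics. The generator validates the *algebra*
of the workflow (indices, thresholds, set algebra, conservation,
interpolation exactness, ordination recovery), not any climatological
claim about a real region.

## Problem sizes and numerical choices

The shipped tests run on grids between 2×2 (worked arithmetic) and 60×60
cells (ordination recovery), with 10⁴ random index triples for the
classification oracle — sizes chosen so the whole suite completes in
seconds while still exercising every code path at meaningful resolution.
Classification is exact integer logic apart from the half-open boundary
convention; interpolation and ordination checks use tolerances of 10⁻⁸ to
10⁻⁹ for algebraically exact identities and looser empirical bounds (e.g.
axis-1 correlation above 0.95) for statistical recovery. Degenerate inputs
are handled explicitly: NaN index values classify to NA, zero positive
temperature flags the ombrotype undefined, a constant seasonal cycle
triggers the documented tie rule, and rank-deficient ordination inputs
drop collinear variables with a warning.

## I/O and limitations

Gridded data are exchanged as tibbles of cell records and, on disk, as
plain-text ESRI ASCII rasters (one file per band, with CSV legends and
metadata sidecars) — a deliberately simple, GIS-readable, diffable format.
Inputs must already be co-registered on one equal-area grid: the package
performs no reprojection or resampling, assumes square cells, and treats
the analysed-cell set (rows present in the table) as the mask. The
classification covers the three-index isobioclimate level only, not the
full hierarchy above or below it; the published 11-row ombrotype table
ships as data and can be extended (e.g. with a hyperarid row) without code
changes.
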