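---
title: "Methods: spatiotemporal NCP supply-demand assessment"
author: "ncpscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal NCP supply-demand assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpscape)
```

## Overview

`ncpscape` quantifies, for every municipality of a region and every decadal
timestep, the supply of and societal demand for six Nature's Contributions
to People (NCPs), combines them into bounded budget and ratio indices,
summarizes each municipality--NCP trajectory by three variables (current
budget, budget slope, ratio slope), and clusters municipalities on the
resulting 18-dimensional feature space into spatiotemporal archetypes. This
vignette documents the models, the tunable parameters and their defaults,
the synthetic study-region generator, and the design decisions taken where
more than one defensible construction exists.

## Indicator models

All indicators operate on a shared raster grid (default 1 ha pixels) with a
zone raster assigning every pixel to exactly one municipality by its center;
the zonal statistic is the pixel mean for index- and density-like
quantities, the pixel sum for mass-like ones. Distances are Euclidean
between pixel centers in projected meters. Every moving-window kernel is
truncated at a finite radius and normalized by the kernel mass actually
inside the grid, which makes a spatially uniform field an exact fixed point
of the smoother (no edge attenuation) and underlies several exact limit
tests.

**Pollination supply** is a two-factor habitat model: abundance at a pixel
is its land-cover nesting suitability times the kernel-weighted mean of
floral resources within foraging range, with `K(d) = exp(-d / alpha)`,
`alpha = 500` m and truncation at `2 * alpha`. Both lookups are
configuration tables covering every land-cover class. **Pollination
demand** is the area-share-weighted pollinator dependence of the
municipality's cultivated classes, rescaled by the maximum attainable
dependence so a municipality growing only the most dependent crop scores 1;
municipalities without cropland score 0.

**Habitat supply** maps protection levels 0--4 to values
`{0, .25, .5, .75, 1}` and averages them per zone. **Habitat demand** is a
threat-degradation model: per threat layer, intensity is kernel-averaged
under a linear (default) or exponential decay clipped at a per-threat
maximum distance (urban 500 m, agriculture 300 m), multiplied by the focal
class's sensitivity to that threat and the threat weight, and summed over
threats. The field is rescaled to [0, 1] by its regional maximum. Within a
multi-timestep run the maximum is taken over *all* timesteps (one shared
denominator): rescaling each timestep by its own maximum would pin every
timestep's worst pixel at 1 and erase the temporal trend that the slope
module later regresses. A single-timestep call uses the field's own maximum.

**Recreation supply** averages three feature layers -- class attractiveness,
a water-proximity flag (within 200 m of open water) and a public-park flag
-- thresholds the result at `theta = 0.4`, and credits retained pixels with
value x pixel area x usable-space fraction `u = 0.5` (m2). The municipal
value is the *zone mean* of these contributions; the alternative reading
(zone sum) is a one-line config change but the mean keeps the quantity
comparable across differently sized municipalities, matching the demand
side. **Recreation demand** is the mean population within walking distance
(uniform disc, `R = 1000` m, normalized by the in-grid buffer size) times a
per-capita recreation need `q = 30` m2/person.

**Food supply** is crop yield (kg/ha) times cultivated area plus livestock
density (animals per pasture-ha) times pasture area times meat yield per
animal. **Food demand** is per-capita consumption (700 kg/person/yr) times
population.

**Water supply** evaluates Fu's form of the Budyko curve per pixel:
`AET/P = 1 + PET/P - (1 + (PET/P)^omega)^(1/omega)`, yield `Y = P - AET`
(mm/yr), with `omega = 2.6` on vegetated classes and 2.0 otherwise, then
converts the zonal mean to m3. Pixels with non-positive precipitation yield
0 with a warning rather than an error. **Water demand** adds per-capita
household use (100 m3/person/yr) times population and per-pixel sectoral
rates by land-cover class.

**Climate supply** uses net primary productivity by land-cover class
(tC/ha/yr) as the carbon-sequestration proxy. When the NPP record exists
only for later timesteps (the satellite-era situation), `npp_backcast()`
completes each municipality's series by OLS on the timestep index, clipping
fills at zero; the pipeline masks timesteps 1--2 by default to mirror that
workflow (`npp_backcast_timesteps`). **Climate demand** converts per-capita
CO2-equivalent emissions (declining from 7.5 to 5.5 t/person/yr across the
four timesteps) to carbon via the molar ratio 12/44.

## Indices

Food, water and climate records are divided by municipal population before
indexing, so city size does not dominate the scale; a zero-population
municipality with nonzero demand is an error rather than a silent Inf.

The **budget** must lie in [-1, 1] and the **ratio** in [-1, Inf). The only
normalization that delivers both printed ranges is: per NCP, min--max scale
supply and demand *jointly* (one shared min and max over both variables,
all municipalities, all timesteps pooled) and subtract; and form the ratio
on raw same-unit values as `S/D - 1`. Pooling across timesteps is essential
-- per-timestep normalization would make the budget slope meaningless.
The `-1` shift makes 0 mean "demand exactly met" and -1 "no supply"; the
unshifted quotient is available via `ratio_shift = FALSE`. Zero-demand
records map to a configurable cap (default 99, flagged) when supply is
positive and to 0 when both vanish. A degenerate NCP (all values equal)
normalizes to zero with a warning.

## Trends

`B_coeff` and `R_coeff` are the OLS slopes of the budget and ratio series
on the ordinal timestep index 0..3. The decadal timesteps are approximately
evenly spaced and only the sign and relative magnitude of slopes are
interpreted, so the ordinal regressor is the default; calendar mid-years
can be supplied (`trend_regressor = "calendar"`). No p-values accompany
4-point regressions -- the slopes are descriptive. A sign classification
(`classify_quadrant()`) labels each municipality--NCP pair
stable-improving, stable-declining, mixed, or neutral; "neutral" needs a
numeric convention and uses a half-width of `eps = 1e-6`, i.e. effectively
only exact zeros, since the coefficients are continuous. The cube-root
transform applied in exported plot data is display-only and never enters
clustering.

## Clustering

The feature matrix has one row per municipality and 3 x 6 = 18 columns.
Columns are z-scored by default: the features mix bounded budgets with
small slope magnitudes, and without standardization the largest-variance
column would dominate the Euclidean metric (a raw-scale option exists for
sensitivity analysis). Ward linkage (`ward.D2`) on Euclidean distances is
the default, the standard choice in ecosystem-service bundle and archetype
analyses; average and complete linkage are available. Visual dendrogram
inspection is replaced by a reproducible criterion -- mean silhouette width
maximized over k = 2..8, ties to the smaller k -- with a manual `k`
override, and a merge-height-gap alternative. Cluster ids are canonical
(descending size, ties by lowest member id) so outputs are invariant to row
order. Profiles report per-cluster means of the *unstandardized* features,
current land-cover composition and a +/0/- sign summary.

## The synthetic study region

The generator emulates the statistical structure the analysis assumes, not
any real geography: a canton-scale miniature (200 x 200 pixels at 1 ha,
about 400 km2) partitioned into 60 municipalities by Voronoi cells around
random seed pixels (guaranteeing a full partition with irregular convex
shapes), four decadal timesteps, and four planted archetypes with distinct
trajectories:

* **urbanizing core** -- settlement grows from ~30% towards 50% at the
  expense of cropland and meadow, parks expand, population density 80
  persons per settlement-ha growing x2.2 over the window;
* **stable highlands** -- forest/meadow dominated, nearly flat transitions,
  density 30, growth x1.15;
* **agro plain** -- cropland-dominated with horticultural intensification
  (raising pollinator dependence), density 25, growth x1.35;
* **blue-green belt** -- lakes, parks and meadows, park expansion, density
  45, growth x1.5.

Class-fraction trajectories follow per-archetype Markov transitions and are
allocated to pixels by fixed per-class suitability surfaces (smoothed
Gaussian fields; settlement and parks keyed to distance from the zone
seed), so class growth is spatially nested and contiguous, and settlement
shares are exactly non-decreasing at zero noise. Population is distributed
within zones by a settlement-weighted kernel and municipal totals are
rescaled so the regional total grows by exactly the configured factor
(default +60% over the window, matching the case-study setting the pipeline
is modeled on). Protected-area networks expand over time at
archetype-specific rates with nested designation order, as real reserve
networks did over these decades. Precipitation and potential
evapotranspiration are static smooth fields (1100 +/- 250 and 650 +/- 80
mm/yr).

`noise_sd` is the log-standard-deviation of a municipality-level
multiplicative perturbation of class fractions, constant in time so that
trend signatures are preserved; ancillary heterogeneity channels
(population density, protected share) use `noise_sd / 2`, keeping
composition the primary stochastic channel. All randomness flows from one
seed through named substreams, so individual layers are reproducible when
others change.

What the generator does *not* emulate: real municipality geometries or
sizes, sub-annual dynamics, climate change over the window, trade or price
effects, spatially autocorrelated population noise, or measurement error in
any input layer. Passing recovery tests on this generator therefore shows
that the pipeline's statistics faithfully propagate planted structure of
realistic magnitude -- not that any particular real region contains four
archetypes.

## Numerical choices and degenerate inputs

* Kernel sums are computed by shift-and-add over precomputed offsets,
  O(offsets x pixels); a brute-force double loop over pixel pairs serves as
  the test oracle on grids up to ~20 x 20 (relative tolerance 1e-9).
* Largest-remainder apportionment turns class fractions into integer pixel
  counts (ties by class order), so zone class counts always sum exactly.
* Voronoi ties go to the lowest municipality id; hclust distance ties are
  resolved on id-ordered rows, making results permutation-invariant.
* Degenerate cases: all-zero threats give zero demand (not an error); a
  constant feature column errors by default (zero-fill on request); `k = 1`
  and `k = n` cuts are legal; empty `k_range` errors.
* Problem sizes in the test-suite: brute-force oracles run on 12--16 pixel
  grids; property tests over 100 seeds use 16 x 16 regions with 5
  municipalities, which probe the identical index algebra at desk-scale
  runtime; archetype-recovery tests run the full 200 x 200 default.

## Known limitations

Only local (within-municipality) supply-demand balances are computed;
proximity and interregional flows are out of scope, as are uncertainty
propagation on the indices, species-level pollinator guilds, groundwater,
and seasonal dynamics. The indicator models are deliberately transparent
stand-ins for the heavyweight engines used in applied studies; they share
the functional form (distance-decay kernels, Budyko curve) but none of the
calibration burden, and absolute magnitudes should not be compared against
calibrated model output.
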