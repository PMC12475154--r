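---
title: "A thermal niche-environment model of Phanerozoic marine biodiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A thermal niche-environment model of Phanerozoic marine biodiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeoniche)
```

## The model and its assumptions

`palaeoniche` simulates marine species richness as the outcome of the
interaction between a fixed pool of one-dimensional thermal niches and a
gridded monthly sea-surface temperature (SST) regime. The assumptions are
deliberately spare:

* a niche *sensu* Hutchinson is reduced to a closed temperature interval
  `[Y - X/2, Y + X/2]`; no other environmental axis, no trophic
  interactions, no dispersal limitation, no explicit origination or
  extinction dynamics;
* biodiversity is evaluated only on the shallow marine cells *around
  continents* (where the fossil record predominantly comes from), under
  eight interchangeable characterisations (1- or 2-cell rings, optional
  <600 / <1000 / <1500 m bathymetry ceilings);
* a niche persists annually in a cell when at least ε of the 12 months are
  thermally suitable;
* allopatric speciation is purely geometric: each fully isolated patch of a
  niche's annual occupancy counts as one potential species, the rationale
  being that full spatial separation interrupts gene flow on the
  multi-million-year spacing of the time slices.

The same pool of niches is reused across all time slices of a run, so all
temporal signal comes from the environment, not from niche evolution.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `alpha`, `beta` | organismal lower/upper thermal limits | °C | −2, 44 |
| `gamma`, `delta` | min/max tolerance breadth (eurythermy) | °C | 4, 20 |
| `n` | niche pool size | — | 100,000 |
| `epsilon` | months required for annual persistence | months | 8 |
| `ring_width`, `depth_limit` | shelf-mask variant | cells, m | 2, none |
| connectivity | patch adjacency | — | 8-neighbour |

α is the freezing point of sea water; β the ceiling for metazoan
reproduction. Breadths are drawn as `X = d1 * (delta - gamma) + gamma`, so
`X` spans `[gamma, delta]` as the definition of the eurythermy parameters
requires; a `breadth_formula = "verbatim"` variant retains the alternative
`X = d1 * (delta - gamma) + delta` (breadths in `[delta, 2*delta - gamma]`)
for comparison, because that variant circulates in print even though it
contradicts the parameter definitions. Suitability uses closed interval
bounds — a measure-zero choice.

A useful consequence of the corrected draw: the probability that a random
niche covers temperature *t* (the *coverage curve*) is symmetric about the
mid-domain `(alpha + beta)/2 = 21` °C, rises steeply on `[-2, 18]`, and is
*flat* on the plateau `[alpha + delta, beta - delta] = [18, 24]` — for any
centre in that band the whole tolerance interval fits inside `[alpha,
beta]` for every admissible breadth, so positional effects vanish. This is
the mid-domain effect in niche space: more species can coexist at
intermediate temperatures for the same area. It also means the *location*
of the empirical coverage maximum is only defined up to the plateau; the
package's acceptance script therefore reports the midpoint of the
near-maximal set (within 2 Monte-Carlo standard errors of the maximum),
which estimates the centre of the true maximal set.

## The synthetic palaeo-world generator

`make_world()` builds time slices with the statistical structure the
analysis assumes, so the entire pipeline is testable without palaeoclimate
downloads:

* annual-mean SST follows `pole + (equator - pole) * cos^2(phi)` — smooth,
  monotonic poleward, qualitatively matching GCM profiles (no analytic
  profile is canonical, so the simplest smooth one is used);
* the seasonal cycle `amplitude * sin(phi) * cos(2*pi*(m - 7)/12)` is
  hemispherically anti-phased (July maximum in the north), zero at the
  equator;
* SST is floored at −2 °C, consistently with α;
* continents are lat-lon rectangles; bathymetry is `shelf_slope` (default
  400 m) per cell of Chebyshev distance from land, capped at an abyssal
  4500 m, which yields controllable <600/<1000/<1500 m shelves;
* each slice draws its noise from an RNG stream derived from `(seed, age)`,
  so slices are independent and order-insensitive, and identical inputs are
  bit-reproducible.

`make_drift_scenario()` interpolates continent rectangles linearly in age
between waypoints; when the continent count changes between waypoints (a
fragmentation event) the older configuration holds until the younger
waypoint is reached, producing a discrete split.

What the generator does *not* emulate: land-sea geometry beyond rectangles,
zonal asymmetries (boundary currents, upwelling), equal-area grids (the
package targets regular lat-lon grids; ingestion of equal-area fields would
require a different adjacency treatment), eustatic sea-level change, and
correlated (red) noise. Tests passing on synthetic worlds therefore
demonstrate the correctness of the *operations* and the qualitative
mechanics of the model, not fidelity to any particular palaeoclimate.

## Numerical and design choices

* **Adjacency.** "Around continents" and patch connectivity are both
  8-neighbour (Chebyshev) with longitude wrap and no polar wrap, with
  4-neighbour variants available. Chebyshev avoids diagonal-coastline
  artefacts in masks; for patches it keeps diagonally touching cells in one
  population, the conservative choice for speciation counts.
* **Two richness definitions.** Maps default to the monthly-mean richness
  (mean over 12 monthly counts); global species counts use the annual
  ε-rule. Both are exposed (`richness_map(mode =)`) because mapping and
  counting are described as distinct steps of the procedure.
* **LCI readings.** The occupied-cell count is taken on the annual
  (ε-qualified) occupancy by default; a `months = "sum"` option counts
  occupied cell-months instead. The two readings of "for all months" are
  both cheap, and neither is asserted to be the original.
* **Patch counting.** Hand-written union-find over shifted-mask edges,
  because off-the-shelf labellers do not wrap the longitude seam and patch
  isolation is the speciation primitive itself. Tests verify it against a
  literal stack-based flood fill. Note a genuine non-monotonicity: raising
  ε shrinks occupancy monotonically, but the per-niche *patch sum* may
  rise when a connected range splits — only occupancy and the
  without-speciation count are monotone in ε.
* **Cell areas.** Closed-form ellipsoidal band areas on WGS-84, divided
  equally among a band's columns; a global grid sums to the Earth's
  surface to well under 0.1 %.
* **Interpolation.** Fossil curves are interpolated with the
  shape-preserving piecewise cubic Hermite method (`pracma::pchip`), which
  reproduces knots exactly and never overshoots on monotone segments;
  extrapolation is refused, and index target ages outside the curves'
  common span are dropped with a warning.
* **Fossil index.** Curves are 0-1 standardised first, then interpolated,
  then column z-scored for a standardised PCA (correlation matrix), in
  that order. The PC1 sign is arbitrary, so the index is oriented to
  correlate positively with the across-curve mean (tie → positive loading
  on the first curve).
* **Corrected significance.** The effective sample size uses
  `1/N* = 1/N + (2/N) * sum_j rho_xx(j) rho_yy(j)` with lag truncation
  `J = floor(N/5)` and biased (1/N-normalised) autocorrelations — the
  common usage of the correction; both choices are exposed. `df_adj` is
  floored at 2 so the t distribution is defined; if the estimated products
  make `1/N*` non-positive the correction is skipped. Simulations in the
  test suite show the corrected test is near-nominal for white noise and
  vastly closer to nominal than the raw test under strong AR(1)
  autocorrelation.
* **Missing months.** Cells with missing SST in a month (e.g. transient
  sea-ice conventions in ingested fields) count that month as unsuitable.
* **Streaming.** Niche projection runs in blocks (`block_size`); results
  are block-size independent, which a test asserts.

## Design of the synthetic experiments

Three experiments (shared by the test suite and the acceptance script)
probe the mechanics the model is meant to express, on a 36 × 36 grid with
5,000 niches and 10 slices — sizes chosen so each experiment completes in
seconds while keeping count differences far above discreteness:

1. **Equatorward drift.** A 20°-tall polar continent drifts from 80°S to
   35°S in 5°-per-slice steps (one grid row per slice, so every slice's
   landmask differs) under a cool gradient climate (equator 22 °C). The
   cool ceiling keeps shelf temperatures on the steep flank of the coverage
   curve for the whole path: with a warmer ocean or a drift ending at the
   equator, two confounds intervene — the coverage plateau saturates, and
   the flattening of `cos^2` near the equator collapses the shelf's
   temperature span (fewer distinct niches intersect it), which can
   legitimately *reduce* richness. The experiment is designed to isolate
   the warm-shelf mechanism; the confound is a real model behaviour, not a
   numerical artefact.
2. **Fragmentation.** One equatorial block versus two half-width blocks
   separated far beyond the mask ring, same climate and land area: the
   patch sum roughly doubles for dual-shelf niches and never decreases.
3. **Climate state.** A pole-to-pole meridional strip provides shelf at
   every latitude; cold (equator 18 °C), reference (28 °C) and hot
   (equator 40 °C, pole 10 °C) climates are compared through an LBG
   steepness statistic (low-latitude mean minus high-latitude mean).
   Cooling steepens the gradient; strong warming flattens and inverts it,
   because equatorial water leaves the niche pool's coverage optimum.

## Interfaces

This is an analysis package: the exported functions are the interface, and
`scripts/acceptance.R` is the runnable entry point that recomputes the
headline quantities from a single `--seed`. Gridded slices exchange through
a self-describing plain-text dialect (`write_world()` / `read_world()`:
header attributes plus one CSV row per cell with landmask, bathymetry and
12 monthly SST columns); niche pools, age series and ledgers are plain CSV.

## Known limitations

* One environmental axis (temperature); everything a richer niche would
  add is out of scope by design.
* Regular lat-lon grids only; no equal-area grid adjacency.
* Rectangle continents in the generator; real coastline complexity enters
  only through ingested fields.
* The fossil-index stage ingests diversity curves as given; no taxonomic
  harmonisation or sampling standardisation.
* Reported headline correlations of the original full-scale analysis
  depend on external forcing fields and databases; the package's own
  checks are property-based at desk scale.
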