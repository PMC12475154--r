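# palaeoniche

Simulating global marine biodiversity and its latitudinal arrangement over
geological time from the interaction between thermal niches and gridded
monthly sea-surface temperatures.

## The scientific problem

Why does marine species richness peak at low latitudes today, and what drove
the rises and falls of the global species pool over the Phanerozoic (the last
541 Myr)? One mechanistic answer is the *niche–environment interaction*: a
species persists where its thermal tolerance interval matches the local
monthly temperature regime, so the latitudinal SST gradient, the position of
continents relative to climate belts, the available shallow-shelf area and
the fragmentation of species ranges jointly set both a carrying capacity and
a spatial pattern for biodiversity.

`palaeoniche` implements this model as a tested, reusable R package, driven
either by gridded palaeoclimate fields (ingested through a plain-text grid
dialect) or by a built-in synthetic palaeo-world generator, so every stage is
testable without climate-model downloads.

## The model

A pool of *N* random rectangular thermal niches is drawn from five
parameters: lower and upper organismal limits α = −2 °C and β = 44 °C,
minimum and maximum tolerance breadths γ = 4 °C and δ = 20 °C, and
*N* = 100,000. Each niche has breadth *X* = *d₁*(δ − γ) + γ and centre
*Y* = *d₂*(β − X/2 − (α + X/2)) + (α + X/2) with *d₁*, *d₂* ~ U(0, 1),
giving the tolerance interval [*Y* − *X*/2, *Y* + *X*/2] ⊂ [α, β].

Per time slice, each niche is projected onto the marine cells *around
continents* (1- or 2-cell rings, optionally depth-limited — eight variants)
using 12 monthly SST layers. A cell is occupied annually when at least
ε = 8 of 12 months are suitable. Without allopatric speciation a niche is
one (pseudo-)species; with it, each isolated patch of the niche's annual
occupancy (8-neighbour connectivity, longitude wrap) is a potential species.
Per-slice indices follow: shelf area on the WGS-84 ellipsoid, latitudinal
biodiversity gradients (LBG), the latitudinal continental index (LCI) and
its LBG-weighted form, and temperature-density diagnostics.

Fossil diversity curves from multiple databases are combined into a *fossil
species richness index*: 0–1 standardisation, shape-preserving (PCHIP)
interpolation to the simulation ages, then a standardised PCA whose oriented
first component is the index. Series are compared by Pearson correlation
with autocorrelation-corrected significance (Pyper–Peterman effective
degrees of freedom, `p_ACF`) and the minimal-df diagnostic `df*` (the
smallest df keeping p ≤ 0.05).

## A worked example

```r
library(palaeoniche)

grid <- grid_spec(36, 36)
pool <- generate_niche_pool(niche_params(n = 5000, seed = 11))

# a polar continent drifting to mid latitudes under a cool gradient climate
cfg <- function(lat) world_config(equator_sst = 22, pole_sst = -2,
                                  seasonal_amplitude = 4,
                                  continents = list(continent(lat, c(-20, 20))))
worlds <- make_drift_scenario(
  list(list(age = 500, config = cfg(c(-90, -70))),
       list(age = 50,  config = cfg(c(-45, -25)))),
  grid, seq(500, 50, length.out = 10))

run <- run_pipeline(worlds, pool)
run$ledger[, c("age_ma", "richness_no_speciation", "richness_speciation")]
```

```
   age_ma richness_no_speciation richness_speciation
1     500                    439                 439
2     450                    712                 718
3     400                   1034                1063
...
10     50                   3058                3283
```

Global with-speciation richness rises strictly from 439 to 3283 species as
the continent's shelf moves into warmer water: warmer shelves intersect more
of the niche pool (up to the mid-domain plateau of the coverage curve), the
core mechanism linking palaeogeography to the global species pool.

```r
idx <- build_fossil_index(
  synth_fossil_curves(seq(540, 0, by = -5), seed = 3)$curves,
  seq(540, 0, by = -5))
idx
#> <fossil_index> PC1 of 5 curves over 109 ages; PC1 explains 78.2%
```

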