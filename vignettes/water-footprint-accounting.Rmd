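---
title: "Simulating green and blue crop water footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating green and blue crop water footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

The water footprint of a crop is the volume of freshwater consumed to
produce it: *green* water taken from precipitation, and *blue* water
taken either from irrigation or from shallow groundwater via capillary
rise. `wfcrop` implements a desk-scale version of the production chain
behind modern gridded water-footprint datasets:

1. a **daily crop-growth and vertical soil-water-balance simulator** that
   traces the three water colours through every compartment of the soil
   profile and into evapotranspiration, yielding per-season crop water
   use (CWU, mm) split by colour and a dry yield (t/ha);
2. **post-processing** that converts dry to fresh yields, projects and
   scales harvested areas to a national census, scales simulated national
   production to the same census, and forms unit water footprints
   (uWF = 10 CWU / yield, m³/t) and production water footprints
   (pWF = uWF × production, m³/yr);
3. **reporting**: allocation of coarse-cell results to a finer grid in
   proportion to harvested areas, production- and area-weighted national
   and decadal aggregation, a 13-column national CSV and NetCDF grids
   with the layer naming used by published datasets;
4. the **validation statistics** used to compare gridded datasets
   (matching-cell fraction with a minimum-value exclusion, plain and
   weighted Pearson correlation, median of grid-level relative
   differences).

Everything runs on a reproducible synthetic world, so the full pipeline
is testable without any external data.

```{r}
library(wfcrop)
run <- wf_pipeline(world_config(seed = 42))
glance(run)
tidy(run)        # national records, published schema
autoplot(run)    # uWF components by country, crop and year
```

## The daily water balance and colour tracing

The soil profile is 3 m deep in eight compartments (0.10–0.70 m thick);
shallow-rooted crops use a 2 m, seven-compartment variant. Each
compartment stores water as three colour masses (green, blue-irrigation,
blue-capillary), so colour conservation is structural and fractions are
derived quantities. Each day applies, in fixed order:

1. **capillary rise** — only for rainfed crops (irrigated fields are
   assumed not to draw on groundwater, flooded rice excepted), zero below
   4 m water-table depth, increasing linearly as the table shallows, with
   an effective minimum depth of 1 m (soils drained to 1 m where the
   table reaches the surface), gated by the sub-field-capacity deficit of
   the deepest compartments above the table, entering as blue-capillary;
2. **rainfall partition** — SCS curve-number runoff
   (`S = 254(100/CN − 1)`, 20% initial abstraction); infiltration fills
   compartments to saturation from the top. Flooded rice fields carry
   0.3 m bunds: rain ponds instead of running off, and only water above
   the bund spills;
3. **irrigation** — for non-rice crops, when root-zone depletion exceeds
   the crop's trigger fraction (0.25–0.50 of total available water) the
   root zone is refilled exactly to field capacity. Rice has no
   threshold: the pond is topped up to 50 mm and the puddled root zone
   kept saturated. Water availability is never a constraint, so blue
   consumption reflects potential net irrigation at field level;
4. **drainage** — a tau-cascade: water above field capacity drains at a
   texture-specific daily rate into the compartment below, carrying the
   donor's colour mix; bottom-compartment drainage is deep percolation.
   Ponded (puddled) rice soils drain at one tenth of the normal rate;
5. **evaporation and transpiration** — soil evaporation from the top
   compartment under two-stage drying (energy-limited within the readily
   evaporable water, then a linearly falling rate down to wilting point);
   transpiration from root-zone compartments in proportion to root
   overlap, reduced by the stomatal stress coefficient. Every millimetre
   removed carries its donor compartment's colour mix; in-season
   evapotranspiration accumulates into green/blue CWU.

Mixing is complete and proportional: an inflow of one colour raises that
colour's mass; any outflow removes all colours in proportion. The test
suite checks this arithmetic against an independent parcel-ledger oracle
in which every inflow is an individually tagged parcel moved through the
same event log.

## Crop growth

Phenology runs on growing degree days,
`GDD = max(0, (min(tmax, Tupp) + clamp(tmin, Tbase, Tupp))/2 − Tbase)`.
Heat-unit requirements are calibrated per cell: the maturity requirement
is the mean cumulative GDD between the reference planting and harvest
dates over the available years, and stages sit at fixed fractions of it
(emergence 5%, maximum canopy 40%, senescence 80%, maturity 100%).
Canopy cover follows the canonical exponential expansion
`CC = CC0 e^{CGC t}` mirrored into an approach to `CCx`, and an
exponential decline in senescence; water stress scales the thermal time
used for expansion. Biomass grows with normalized transpiration,
`ΔB = WP* · f_CO2 · Tr/ET0`, and dry yield is `B · HI0` reduced by heat
failure during flowering and severe water stress during yield formation.

Calendars adjust to the weather: emergence waits (up to 30 days) for a
moist seedbed; warm years mature earlier; cold years may extend an
annual season up to 1.15 × its reference length, after which it is
terminated with the accumulated biomass. Deciduous perennials replace
planting with a bud-break date (10-day running GDD threshold), keep
rooting constant and hold a minimum canopy during the leafless period;
evergreen perennials keep a near-static canopy and are harvested every
31 December. Perennial CWU accumulates over the whole calendar year.
Fallow periods simulate a static cover crop (CC 0.30, Kcb 0.60, 0.3 m
roots) so soil moisture — including stored blue water — carries over
between seasons. Results are attributed to the harvest year, so a
winter-sown crop planted in October reports under the following July.

### Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `irrigation_threshold` | fraction of TAW | 0.25–0.50 by crop | least stress-sensitive crops (the C4 cereal) tolerate 50% depletion; sensitive ones trigger at 25–35% |
| `p_up` | fraction of TAW | 0.45–0.60 | depletion where stomatal stress begins; expansion stress engages at 0.7 `p_up` |
| `WP_star` | t/ha per unit ΣTr/ET0 | 0.14–0.32 | C4 crops roughly double C3 water productivity |
| `co2_sens` | – | 0.2 (C3), 0.04 (C4) | saturating CO2 response: about +10% (C3) / +2% (C4) at +200 ppm above the 369.41 ppm reference |
| `tau` | day⁻¹ | 0.4–0.8 by texture | drainage cascade rate; clay drains slowest |
| `cn` | – | 72–83 by texture | daily curve number |
| `cr_max` | mm/day | 2 | capillary-rise flux at 1 m water-table depth, falling linearly to 0 at 4 m |
| bund height | mm | 300 | rice bunds suppress runoff until ponding exceeds them |
| pond target | mm | 50 | flooding depth maintained for irrigated rice |

## The synthetic world

`generate_world()` builds a miniature input stack with the structure the
pipeline assumes: a 4×4 coarse simulation grid subdivided ×2 into the
allocation grid, three contiguous countries spanning a humid (1200 mm/yr)
to semi-arid (500 mm/yr) gradient, 12 years of daily weather (two of
which are warm-up), soils from a three-class pedotransfer table, a
monthly groundwater climatology with both shallow (<2 m) and deep (>4 m)
cells, five crop archetypes (annual C3 cereal, low-sensitivity annual
C4, paddy rice, deciduous perennial, evergreen perennial), per-crop
rainfed/irrigated area maps, linear per-country-crop area trends and a
linear CO2 series. Weather uses a first-order two-state wet-day chain
with gamma amounts — daily intermittency is what the water balance is
sensitive to — a sinusoidal temperature cycle with AR(1) noise, and
shortwave radiation that co-varies negatively with wet days. All
randomness derives from one root seed through named substreams, so
adding a component never perturbs another's draws.

The census is synthesised *from the simulated truth*, perturbed by a
configurable relative noise (default 5%). This is deliberate: with zero
noise the census equals the pipeline's own bookkeeping exactly, so every
area and yield scaling factor collapses to 1 — a self-consistency
recovery check that a hand-written census could not provide.

What the generator does **not** emulate: real geography and coastlines,
bias-corrected reanalysis forcing, historical CO2, multi-season cropping
calendars, interannual groundwater dynamics, or the long tail of crop
diversity. Passing tests therefore demonstrate the internal consistency
and stated properties of the method — colour conservation, scaling
exactness, schema fidelity, metric correctness — not agreement with any
real-world dataset.

## Numerical and design choices

* **Event order** within a day (capillary rise → rain → irrigation →
  drainage → ET) is fixed; daily closure per colour holds to 10⁻⁶ mm.
* **Evaporation stage** is diagnosed from the current top-compartment
  depletion rather than a wetting-event counter, and supply stops at
  wilting point; this keeps the step stateless and makes the
  at-wilting-point limit exact.
* **Capillary-rise law** (linear in depth, 4 m cutoff, 2 mm/day at 1 m,
  dryness-gated, applied to the deepest unsaturated compartments) is a
  canonical form; upstream models do not publish theirs.
* **Infiltration excess** once the profile (or puddled zone) saturates
  becomes surface runoff, never silent clipping; `mix_inflow()` refuses
  overfill by classed error so routing bugs cannot hide.
* **Stress-to-yield combination**: heat failure scales the harvest index
  by `max(0.05, 1 − failed/window)` over the flowering window (40–55% of
  maturity GDD); water stress scales it by `0.2 + 0.8 · mean Ks` over
  yield formation (55–90%). These dose-responses are package choices,
  parameterised and documented, not inherited values.
* **Degenerate inputs**: zero-yield cells mask uWF as `NA` (written as
  NetCDF fill values, never 0); countries with zero simulated production
  but positive census are flagged with an undefined scaling factor; cells
  that accumulate no heat units are declared non-viable.
* **Ties and caps**: seasons still in progress at the simulation end are
  dropped; the season cap is `ceiling(1.15 L)` days after planting.

Problem sizes: the default world (16 coarse cells, 5 crops, 2 systems,
12 years) runs the full pipeline in roughly a minute and a half on one
core; the test suite uses a 2×2 five-year world for most pipeline
properties and the default world for the end-to-end acceptance checks.

## Limitations

Nutrient cycles, soil fertility, salinity, pests, crop rotation and
multi-cropping are out of scope, as are grey water footprints,
groundwater pumping dynamics, conveyance losses and water-availability
constraints (blue consumption is potential, not actual). A single
archetype parameter set stands in for the hundreds of real crops; only
heat units are calibrated per cell. The capillary-rise and stress
dose-response forms are canonical substitutes where the literature
leaves the functional form unspecified, and conclusions sensitive to
those forms should be tested against their parameters.
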