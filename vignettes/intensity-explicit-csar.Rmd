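---
title: "Intensity-explicit countryside species-area modelling with csarlui"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intensity-explicit countryside species-area modelling with csarlui}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csarlui)
```

## The model

The classical species-area relationship (SAR) treats all human-used land
as lost habitat. The countryside SAR (cSAR) relaxes this: land under use
still contributes habitat, but its area is discounted by an *affinity*
of the native species pool to that land-use type. For a taxonomic group
in grid cell $n$ with potential (pristine-condition) richness
$S^{pot}$, predicted loss is

$$
S^{loss} = S^{pot}\left(1 -
  \left(\frac{A^{cur} + \sum_b h_{b}\,A_{b}}{A^{pot}}\right)^{z}\right),
$$

where $A^{pot}$ is the cell's terrestrial area, $A^{cur}$ the remaining
pristine area, $A_b$ the area of land-use type $b$, $z \in (0,1)$ the
cell's SAR exponent, and $h_b \in [0,1]$ the affinity of the pool to
type $b$. A wilderness cell ($\sum_b A_b = 0$) loses nothing; a fully
converted cell with $h = 0$ loses its whole pool.

The affinity has two parts,

$$
h_{b} = r_{b}^{1/z}\; f(\mathrm{LUI}_{b})^{1/z},
$$

* $r_b$ — the fraction of the cell's refined pool affiliated with type
  $b$ (`compute_affinity_fractions()`). For the two *unconverted* broad
  types, grazing land and forests, use happens without prior conversion
  and every native species counts as affiliated, so $r = 1$ there.
* $f(\mathrm{LUI})$ — the fraction of those affiliated species that
  persists at the type's management intensity, a piecewise-linear
  response over the scaled intensity index
  (`build_response_function()`).

Because both parts enter through the $1/z$ power, they act on the
*effective habitat area* rather than directly on richness; the $f = 1$,
$r = 1$ limit makes used land indistinguishable from pristine habitat,
and the model then predicts zero loss (a property the test suite checks
explicitly).

### Conversion versus intensity

Running the model a second time with all intensities forced to zero
($f = 1$, $h = r^{1/z}$) isolates the pure land-conversion effect
$S^{loss\,conv}$. The intensity contribution is reported relative to the
pool,

$$
S^{loss\,int} = \frac{S^{loss} - S^{loss\,conv}}{S^{pot}},
$$

so the relative total always decomposes exactly into the two components
(`decompose_conversion_intensity()`; the identity is asserted to 1e-12).
A third, deliberately coarse counterfactual forces $\mathrm{LUI} = 1$
everywhere with the land-use extent unchanged
(`run_scenario(..., "full_intensification")`), bounding what further
intensification of today's used land could cost.

## Species pools and area of habitat

`refine_species_pool()` converts species records (range cell sets,
habitat affiliations, elevational limits) into per-cell pools using the
area-of-habitat (AOH) logic: a species is native to a cell when its
range covers the cell, it is not exclusively aquatic, it is adapted to
the cell's pristine ecosystem class, and its elevational range overlaps
the cell's. Elevation overlap is closed-interval — ranges that merely
touch count as overlapping; this is the permissive reading of an
"overlap" criterion without a stated boundary convention, and the choice
only matters for exact-boundary cases. The species' native AOH is the
area sum of its refined range; it is the denominator of every
per-species loss fraction.

## Intensity indices

Two independent indicator sets quantify management intensity per cell
and fine land-use type, reflecting the two main ways intensity is
operationalised in global data products:

* **Set 1 (HANPP-based)** — the ratio of harvested/extracted biomass to
  the NPP of potential natural vegetation. Built-up land uses a constant
  ratio of $\tfrac12 \times \tfrac13 = 1/6$ (half of an actual NPP that
  is one third of potential). Grazing intensity is limited by the NPP
  accessible to grazers: 50% of potential NPP is removable aboveground,
  of which 30% (closed canopy) or 100% (open land) is non-woody, and the
  maximum harvestable fraction ramps linearly from 40% at 20 gC/m² to
  80% at 250 gC/m² of accessible NPP (clamped outside the ramp — the
  two anchors are all that is specified, and extrapolation would leave
  the physical range).
* **Set 2 (input/output metrics)** — nitrogen application rates on
  crops (kg N/ha), ruminant livestock density on pastures and grazing
  land, built-up density fraction, and forest harvest allocated within
  countries in proportion to each cell's potential-minus-actual biomass
  gap (`allocate_forest_harvest_by_biomass_gap()`, which conserves
  national totals exactly).

Raw indicators are *winsorized* at a saturation threshold — the
intensity beyond which no further richness loss is assumed — and then
divided by it (`winsorize_and_scale()`), giving an index
$\mathrm{LUI} \in [0,1]$. Thresholds: 100% of potential NPP on cropland
and 30% on forests (times a per-biome belowground factor, neutral 1 by
default — real-data users should supply biome-specific values) for
Set 1; removal of all grazing-accessible NPP for Set 1 grassland; 150 kg
N/ha for crops, reduced for nitrogen-fixing legumes (beans/lentils 110,
chickpeas 100, soybean 70, cowpeas/pigeon peas/other pulses 90); the
per-biome 80th percentile of livestock density for Set 2 grassland.
Set 2 built-up density is already a fraction and passes through
unwinsorized. Set 2 forest harvest has no published saturation point;
the package normalises by the per-type maximum of the allocated harvest,
a synthetic-data convention that real-data users should override with a
defensible threshold.

### The response function

Published local-assemblage models estimate richness at three categorical
management levels (Minimal, Light, Intense) for four broad response
classes. The package anchors these at scaled intensities 0.17, 0.5 and
0.83 — the midpoints of the three tertiles of the scaled gradient — and
interpolates linearly, with the ratios $s_{light} =
Est_{Light}/Est_{Minimal}$ and $s_{intense} = Est_{Intense}/Est_{Minimal}$
at the upper two anchors. Below 0.17 the response is held at 1 (all
affiliated species persist under minimal management — this is what the
affiliation data mean); above 0.83 it is held at $s_{intense}$, because
extrapolating beyond the measured intensity range is not defensible.
Ratios above 1 (apparent richness gains under intensification) are
clipped to 1 with a warning, since $f$ is a surviving fraction. The
shipped coefficient table (`default_response_coefficients()`) is a
synthetic default with plausible orderings (urban most severe, pasture
least); real analyses must substitute published estimates.

Fine types (up to 45) carry their own intensity surfaces, but the
response function varies only across the four response classes; the
affinity is evaluated per fine type and results are aggregated to the
six broad reporting types (cropland, pastures, grazing land, builtup,
plantations, forests).

## From cell counts to individual species

The cSAR predicts *how many* species each cell loses, not *which*.
`run_aoh_draws()` bridges this with a randomisation:

1. Per cell, the conversion and intensification loss counts are
   apportioned to fine types proportionally to each type's habitat
   deficit (total $\propto A_b(1-h_b)$, conversion
   $\propto A_b(1-r^{1/z})$, intensity
   $\propto A_b\,r^{1/z}(1-f^{1/z})$; each component normalised to its
   own cell total). The model itself does not dictate an attribution
   rule; this proportional rule was chosen because it is exact in the
   $z = 1$ limit and sums correctly for all $z$.
2. Targets are *stochastically rounded*: rounded up with probability
   equal to the fractional part, preserving expectations and avoiding
   the systematic suppression of sub-0.5 losses in species-poor cells.
   Rounding happens per (cell, type, cause) and per run, the only
   granularity at which the draw loop needs integers.
3. Within each cell, types are visited in a random order (fresh per
   run); conversion losses are drawn uniformly without replacement from
   the species *not* affiliated with the type, intensification losses
   from the affiliated ones; a species can be lost at most once per
   cell, so the visiting order matters — hence its randomisation.
   Within a type's visit, conversion is processed before
   intensification; the two causes draw from disjoint lists, so this
   fixed order is inconsequential for converted types, and unconverted
   types have no conversion targets at all. If a target exceeds the
   eligible list, the whole list is drawn and the shortfall is logged.
4. One hundred runs (the default) give, per species, 100 lost-area
   sums; their mean and empirical 0.025/0.975 quantiles (type-7 linear
   interpolation — no estimator is mandated, and the R default is the
   least surprising) divided by the species' native AOH yield the
   proportional AOH loss with a 95% interval. Species whose interval
   reaches 100% are flagged as facing impending global extinction.

Per-run seeds are derived deterministically from a master seed and the
run index, and every generator component has its own named random
stream, so outputs are bit-identical under a fixed seed and insensitive
to the order in which species are supplied.

## The synthetic landscape generator

`generate_landscape()` is first-class, tested code that emulates the
*statistical structure* of a gridded land-use/biodiversity stack — not
its geography. The defaults define the study conditions used throughout
the tests and the demo pipeline:

* cells are abstract (no projection handling): terrestrial areas
  log-normal around 8.6e7 m² (a mid-latitude 5-arcmin cell), SAR
  exponents uniform in 0.15–0.35, three ecosystem classes, two biomes
  and regions;
* each cell's used share is Beta-distributed with mean 0.4 and
  concentration 10, split across up to 8 fine types drawn from the
  45-type catalogue; 15% of cells are wilderness; the pristine remainder
  closes the land accounting exactly;
* species ranges are contiguous cell blocks with log-uniform sizes (so
  genuinely small-ranged species exist, which is what makes the
  AOH-loss-versus-range-size behaviour probe-able), affiliation
  probability 0.5 per converted broad type, ecosystem affiliation
  probability 0.7, 2% exclusively aquatic;
* Set 1 ratios are uniform within per-type plausible ranges (built-up
  pinned at 1/6; grassland bounded by the accessible-NPP cap); Set 2
  nitrogen rates and livestock densities are log-normal (medians 60 kg
  N/ha and 0.5 LU/ha), and forest harvest is generated through the
  biomass-gap allocator itself.

What the generator does *not* emulate: spatial autocorrelation,
realistic range shapes, taxonomic richness gradients, empirical
intensity distributions, or presence/origin/seasonality coding of
ranges. Passing tests therefore demonstrate the correctness of the
machinery under controlled conditions — closure, determinism, analytic
anchors, distributional targets — not the realism of any global number.

`generate_known_truth_case()` complements this with hand-built
landscapes whose outputs are known in closed form (a half-converted
single cell, an all-minimal-intensity landscape, a two-species draw
oracle); the test suite compares the pipeline against these and against
an independently written scalar implementation of the loss formula on a
thousand random cells.

## Numerical choices and degenerate inputs

* Land-accounting closure is enforced at relative tolerance 1e-9;
  violations name the offending cell.
* Cells with an empty refined pool are flagged and excluded from all
  averaged summaries; empty summary scopes report missing values, never
  zeros.
* The habitat ratio is clipped at 1 before exponentiation so float
  noise in closed landscapes cannot produce negative losses.
* Types with zero area are skipped when building affinities (no
  $0^{1/z}$ evaluations).
* All relative losses keep full floating precision internally and are
  only formatted at export.

## Problem sizes

The bundled demo configuration (also what `scripts/acceptance.R` runs)
uses 400 cells, 100 species, 45 fine types, both indicator sets, three
scenarios and 100 draw runs; it completes in a few seconds on one CPU.
Property tests use 1000-cell landscapes for the identity and oracle
checks and 10,000 repetitions for the rounding and draw-frequency
checks, sizes at which three Monte-Carlo standard errors are tight
enough to detect real defects.

## Limitations

* The shipped response coefficients, type catalogue and habitat
  cross-walks are synthetic defaults; every real analysis must supply
  published coefficients and real mapping tables.
* The per-type attribution rule and the Set 2 forest threshold are
  package conventions (documented above), not community standards.
* Losses refer to an equilibrium with all extinction debt paid, count
  only species native to the pristine ecosystems, and ignore
  immigration — the same interpretive caveats as any cSAR application.
* Raster geometry is out of scope: cells are rows with areas. Ingesting
  real rasters means flattening them to the documented CSV contract
  first.
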