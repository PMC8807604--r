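# csarlui

Intensity-explicit countryside species–area modelling of land-use-driven
native species loss.

`csarlui` is for macroecologists and biodiversity modellers who want to
estimate how many native terrestrial vertebrate species a landscape
stands to lose under its current land use — and to split that loss into
the part caused by *converting* pristine ecosystems and the part caused
by the *intensity* of management on used land, including land that was
never converted (grazed natural grassland, harvested natural forest).

## The model

The countryside species–area relationship (cSAR) counts used land as
partial habitat. For each grid cell with potential richness S^pot,
terrestrial area A^pot, pristine remainder A^cur and land-use areas A_b:

    S^loss = S^pot * (1 - ((A^cur + Σ_b h_b A_b) / A^pot)^z)

with z the cell's SAR exponent and the affinity of the species pool to
land-use type b

    h_b = r_b^(1/z) * f(LUI_b)^(1/z)

where r_b is the fraction of the pool affiliated with type b (r = 1 for
the unconverted types grazing land and forests) and f(LUI) a
piecewise-linear response of richness to a land-use-intensity index
scaled to [0, 1]. Two indicator sets quantify LUI: Set 1 uses the ratio
of harvested biomass to potential NPP (the HANPP framework); Set 2 uses
input/output metrics (nitrogen application, livestock density, built-up
density, biomass-gap-allocated forest harvest). Re-running the model
with LUI = 0 isolates the conversion component:

    S^loss_int = (S^loss - S^loss_conv) / S^pot

Cell-level loss counts are turned into per-species area-of-habitat (AOH)
loss by stochastic rounding plus randomized draws from per-type
affiliated/unaffiliated species lists, repeated 100 times for 95%
confidence intervals. A synthetic-landscape generator makes the whole
pipeline testable without any external data.

## Worked example

```r
library(csarlui)

# the piecewise-linear intensity response for the cropland class
f <- build_response_function(default_response_coefficients())
round(f(c(0, 0.17, 0.5, 0.83, 1), "cropland"), 3)
#> [1] 1.0 1.0 0.8 0.6 0.6

# a full synthetic run: 400 cells, 100 species, both indicator sets
res <- run_pipeline(list(
  synthetic = list(n_cells = 400L, n_species = 100L),
  aoh_runs = 100L, seed = 3L
))
res
#> <csar_pipeline_result> 400 cells, 100 species; sets: Set1, Set2
#>   Set1: mean loss 9.61% (conversion 7.02 + intensity 2.59 %-pts)
#>   Set2: mean loss 9.28% (conversion 7.02 + intensity 2.27 %-pts)
```

The per-set lines are cell-area-weighted means over all non-wilderness
cells with native species: under this synthetic landscape's current land
use, Set 1 predicts that an average landscape eventually loses 9.61% of
its native vertebrate species, of which 7.02 percentage points are due
to land conversion and 2.59 to management intensity. The conversion
component is identical across sets because both share the same land-use
areas; only the intensity surfaces differ.

Per-species AOH loss with confidence intervals:

```r
aoh <- res$aoh$Set1
head(aoh[order(-aoh$mean_loss_fraction),
         c("species_id", "taxon_group", "mean_loss_fraction",
           "ci_low", "ci_high")], 3)
#> # A tibble: 3 × 5
#>   species_id taxon_group mean_loss_fraction ci_low ci_high
#> 1 sp_0096    mammals                  0.32       0   1
#> 2 sp_0026    amphibians               0.302      0   1
#> 3 sp_0054    birds                    0.254      0   0.736
sum(aoh$impending_global_extinction)
#> [1] 10
```

`sp_0096` loses on average 32% of its native area of habitat across the
100 randomized draw runs, and its 95% interval reaches 100% — it is one
of 10 species flagged as facing impending global extinction under this
landscape's land use.

A thin shell wrapper exposes the same machinery
(`exec/csarlui generate ...`, `exec/csarlui run-all --config cfg.yaml`),
and `run_pipeline()` accepts a YAML config with an `out_dir` to write
every intermediate table as CSV plus a provenance log.

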