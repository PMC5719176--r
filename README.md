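# holorange

Range-loss reconstruction and extinction-selectivity models for regional
faunas across postglacial time.

Modern distribution data describe survivors of an *extinction filter*:
the most vulnerable populations vanished long before anyone surveyed them.
holorange rebuilds the missing baseline. Given presence-only locality
records from long-term archives (zooarchaeological and palaeontological
sites; historical observations) and published current-day range polygons,
it reconstructs per-species extent-of-occurrence (EOO) polygons for three
ordered time slices — Holocene (11,700 BP – AD 1900), historical
(AD 1900–2000) and modern (post-AD 2000) — and models the resulting losses
at two levels. It is written for macroecologists and conservation
biogeographers who want the whole chain (I/O, geometry, grids, models,
synthetic benchmarks) reproducible in one place.

## What it computes

**Reconstruction.** Ranges are built cumulatively on the modern baseline:
each older locality point outside the baseline is connected to its two
nearest admissible features (other outside points, the nearest baseline
polygon part, or the country border as fallback, anchored at the
perpendicular foot), each connection realized as the attachment triangle
(point, anchor₁, anchor₂); the layer is dissolved and clipped to the
border. Areas are measured in a Lambert cylindrical equal-area projection
(spherical earth, R = 6371.0072 km), so nesting

&nbsp;&nbsp;&nbsp;&nbsp;A_hol ≥ A_hist ≥ A_mod

holds by construction, and the interval losses are
p = (A_old − A_new)/A_old.

**Gridded loss.** A 100 × 100 km equal-area grid yields per-period species
richness (presence = any positive-area overlap) and per-cell proportion of
species lost per interval, analysed only in cells holding at least one
older-period record (the sampling-bias filter).

**Species-level selectivity.** PGLS regressions of proportion of range
lost (pre-1900 and post-1900, both on the Holocene base) on log₁₀ body
mass and trophic level (1 = herbivore, 2 = omnivore, 3 = carnivore):
GLS with residual covariance λC (Pagel's λ, profile-ML by default),
model set {mass}, {mass + trophic}, {mass × trophic}, {trophic}, ranked by
AICc with the ΔAICc < 2 support rule.

**Cell-level selectivity.** Ten fixed binomial GLMs (models a–j) of the
per-cell (lost, retained) counts on six environmental predictors
(elevation, Human Footprint Index, precipitation, temperature, AET, PET),
ranked by AICc and scored by proportion of deviance explained.

**Synthetic benchmarks.** A seeded generator produces a complete study
system — correlated predictor surfaces, a phylogeny, trait-driven nested
true ranges, presence-only locality samples, known cell-level logistic
coefficients — with ground truth recorded, so every stage's parameter
recovery is auditable.

## Worked example

The bundled table of Holocene / twentieth-century / current-day range
areas for 34 Chinese mammal species drives the aggregate accounting:

```r
library(holorange)
t1  <- china_mammal_ranges()
# two species already had no range by 1900, so their historical-modern
# interval proportion is undefined (warned, flagged NA)
tab <- suppressWarnings(
  area_table(species = t1$species, area_hol = t1$area_hol_km2,
             area_hist = t1$area_hist_km2, area_mod = t1$area_mod_km2))
str(range_loss_summary(tab))
#> List of 5
#>  $ pct_lost_total       : num 22.8
#>  $ pct_lost_pre1900     : num 15
#>  $ pct_lost_post1900    : num 7.79
#>  $ pct_species_lost_lt50: num 73.5
#>  $ n_species            : int 34
```

22.8% of the fauna's combined Holocene range is gone — 15.0% lost before
AD 1900 and 7.8% since — yet 73.5% of species retain more than half their
Holocene range.

A fully synthetic end-to-end run (simulate → reconstruct → grid → both
model suites) is one call:

```r
rep1 <- run_pipeline(list(
  simulate = list(seed = 7, n_species = 12, border_size_km = 2000,
                  raster_res_km = 50, n_sites_holocene = 15,
                  n_sites_historical = 20, area_range_km2 = c(5e4, 5e5),
                  beta0_pre = -0.5, beta0_post = -1.5),
  outdir = tempfile()))
print(rep1)
#> holorange pipeline report
#>   species included: 12 of 12
#>   total Holocene range lost: 6.6% (5.6% pre-1900, 1.0% post-1900)
#>   species losing <50%: 91.7%

rep1$trait_models$pre1900$ranking[, c("model", "LL", "k", "dAICc", "adj_r2")]
#>                                     model     LL k dAICc  adj_r2
#> 1                               body mass  7.438 4  0.00  0.5419
#> 2               body mass + trophic level 12.486 6  4.99  0.9532
#> 3                           trophic level  2.959 5 15.24 -0.1382
#> 4 body mass + trophic level + interaction 13.647 8 37.87  0.9486
```

The generator's mass effect is positive, and the top-ranked pre-1900 model
is indeed the body-mass model. Per-species areas, per-cell loss tables,
the spatial-suite ranking and a checksummed `run_manifest.json` are
written under `outdir`.

## Layout

- `R/` — geometry engine and projection, locality/polygon/trait/tree/raster
  I/O, range reconstruction, grids, PGLS and GLM suites, synthetic
  generator, pipeline orchestration
- `inst/extdata/` — 34-species range-area table; schematic (synthetic)
  China-like demo border
- `tests/testthat/` — unit, property and acceptance tests (closed-form,
  Monte-Carlo and nlme oracles)
- `vignettes/range-loss-reconstruction.Rmd` — methods and design notes
- `scripts/acceptance.R` — headline-number reproduction
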