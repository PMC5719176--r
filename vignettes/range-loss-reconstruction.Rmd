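---
title: "Reconstructing postglacial range loss: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing postglacial range loss: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holorange)
```

## The problem

Current-day distribution data describe a fauna that has already passed
through an *extinction filter*: the populations most vulnerable to human
pressure disappeared first, so correlates of risk estimated from modern data
alone are biased. holorange implements an analysis chain that pushes the
baseline back through the postglacial record. It reconstructs per-species
extent-of-occurrence (EOO) polygons for three ordered time slices — the
Holocene (11,700 BP to AD 1900), the historical period (AD 1900–2000) and
the modern period (post-AD 2000) — from two very different kinds of
evidence: published modern range polygons, and presence-only locality
records (zooarchaeological and palaeontological sites; historical
observations) for the two older periods. On top of the reconstructed ranges
it quantifies *who* lost range (species-level trait models) and *where*
range was lost (cell-level environmental models).

## Range reconstruction

Ranges are built cumulatively, oldest last:

1. The modern baseline is the published range polygon, minus any parts
   flagged as recently extinct (those parts are historical evidence and are
   merged into the historical baseline), clipped to the country border.
2. The historical range extends the modern baseline with the historical
   locality points; the Holocene range then extends the historical range
   with the Holocene points. Nesting `modern ⊆ historical ⊆ holocene` is
   therefore structural, and areas satisfy `A_hol ≥ A_hist ≥ A_mod` by
   construction.
3. A locality point already inside the baseline contributes nothing. A
   point outside it is connected to its **two nearest admissible
   features**: the other outside points of the same layer and the nearest
   part of the baseline multipolygon (anchored at the nearest point on its
   boundary). If fewer than two such features exist, the country border
   fills in, anchored at the foot of the perpendicular from the point to
   the border — the conservative way to acknowledge that most species also
   range beyond the border while asserting nothing about how far.

A straight-line connection bounds no area, so each connection pair is
realized as the *attachment triangle* spanned by the point and its two
anchors — the smallest-area polygon consistent with "connect to the two
nearest features". Collinear triples degenerate to a corridor: the two
connection segments buffered by a half-width `epsilon` (default 10^-6 of
the border's bounding-box diagonal, i.e. metres at a continental scale).
All attachments are computed against the *original* baseline, and the layer
is then dissolved in one union and clipped to the border. Consequences
worth knowing:

* The result is independent of the order in which points are processed
  (asserted by test), and rebuilding is bit-identical.
* Reconstruction from finite samples is conservative: the reconstructed
  area never exceeds what the evidence plus the baseline support, and in
  simulations the deficit against the true range shrinks steadily as
  sampling effort grows (at 50 localities the triangle realization still
  recovers only part of a wide contraction annulus — a feature, not a bug,
  for an evidence-bounded estimator).
* Area is **not** monotone in the point set: a newly added point can become
  the nearest feature of an existing one and re-anchor it away from a
  distant border connection, shrinking the union slightly. What is
  guaranteed — and tested — is containment: every layer contains its
  baseline and every input point.

### Projection and areas

All geometry lives in a Lambert cylindrical equal-area projection on a
spherical earth (R = 6371.0072 km, standard parallel 0°, central meridian
configurable; 105°E centres a China-like region, synthetic landscapes use
0°). Because `x` depends only on longitude and `y` only on `sin(latitude)`,
spherical areas are preserved exactly; the closed-form check against the
spherical band `R²·Δλ·Δsin(φ)` is part of the test suite. Boolean polygon
operations are delegated to the Clipper library (polyclip), which quantizes
coordinates at ~10^-9 relative; measured areas of structurally nested
layers can therefore invert by a few thousandths of a km², and the package
snaps such sub-quantization inversions (anything larger is an error, not
snapped).

### Per-species and aggregate accounting

`proportion_lost(A_old, A_new) = (A_old − A_new)/A_old` per interval; a
species with no range in the older period has no defined proportion and is
flagged `NA` rather than silently dropped. The aggregate summary pools
areas across species on the combined Holocene base, so the pre-1900 and
post-1900 components sum to the total loss. The bundled
`china_mammal_ranges()` table (34 species) reproduces the published
aggregate accounting — 22.8% of combined Holocene range lost, 15.0% before
and 7.8% after AD 1900, 73.5% of species losing under half their range —
exactly from its printed per-species areas.

## Gridded richness and per-cell loss

A grid (default 100 × 100 km) tiles the projected border's bounding box
from its lower-left corner; partial edge cells are kept, cells not touching
the border are dropped. Presence is *any positive-area overlap* between a
species' period range and the cell — not a centroid rule — because it is
the least surprising reading and is monotone under the nested layers. The
per-cell response for interval models is the pair (species lost, species
retained) out of the older period's species.

The archival record is spatially uneven, so a cell enters an interval's
analysis only if it contains at least one locality record of the older
period (Holocene records for the pre-1900 analysis, historical records for
the post-1900 one). Without this filter, unsampled cells would read as
loss-free and regional declines would be underestimated.

## Species-level models: PGLS with AICc

The trait analysis asks whether body mass and trophic level predicted range
loss, and whether that changed over time. The two responses are the
fraction of the Holocene range lost before AD 1900, `(A_hol − A_hist) /
A_hol`, and the further fraction lost after, `(A_hist − A_mod) / A_hol` —
both on the Holocene base so the two eras are additive (this also matches
the aggregate accounting convention). The model set is fixed: {mass},
{mass + trophic}, {mass × trophic}, {trophic}.

Shared ancestry makes species non-independent, so models are fitted by
generalized least squares with residual covariance proportional to the
phylogenetic covariance `C` (shared root-to-MRCA path lengths), with
Pagel's λ multiplying the off-diagonals. Implementation choices:

* σ² is profiled out by maximum likelihood; λ is per-model profile-ML on
  [0, 1] by default (a fixed λ is available). Per-model λ means
  log-likelihoods of nested models need not be monotone — the suite can
  legitimately show a smaller model with a higher LL.
* With λ = 0 or a star phylogeny the fit reduces to OLS exactly (tested to
  10^-8), and the implementation is cross-checked against
  `nlme::gls(correlation = ape::corPagel(...))` on simulated data.
* Body mass is log10-transformed by default (masses span four orders of
  magnitude); trophic level is an unordered three-level factor with
  herbivore as reference, following the 1/2/3 coding; a numeric coding
  exists for sensitivity.
* AICc uses `k` = number of regression coefficients + 1 (σ²) + 1 when λ is
  ML-estimated. Published tables are rarely explicit about this convention,
  so it is an argument, not a constant. Models within ΔAICc < 2 of the best
  are flagged supported; a secondary threshold (default 6) is also
  reported.
* Proportions are modelled untransformed, as in the species-level analysis
  this mirrors; a logit response is a one-line sensitivity via the data
  frame.

## Cell-level models: a fixed binomial GLM suite

Ten predictor combinations of six surfaces (elevation, Human Footprint
Index, annual precipitation, annual temperature, actual and potential
evapotranspiration) encode distinct hypotheses; they are fitted as
logit-link binomial GLMs on the per-cell (lost, retained) counts, so richer
cells carry proportionally more weight. The source analysis names both a
logit-transformed response and a binomial error structure, which are
mutually exclusive; the binomial count model is the default here because it
is the stated error structure, and the empirical-logit Gaussian variant
(`log((p + a)/(1 − p + a))`, `a = 0.5/n`) is retained as a sensitivity
mode. Predictors are z-scored internally (coefficients reported on both
scales); goodness of fit is the proportion of deviance explained,
`1 − D_resid/D_null` — reported as a proportion and labelled as such.
Ranking uses AICc by default with plain AIC a flag, since the source names
both. Model failures inside the suite are recorded and skipped, not fatal.

## What the synthetic generator does and does not emulate

`sim_config()` defaults describe the study conditions: a fauna of 34
species on an abstract 3000 × 3000 km square country; Holocene range areas
0.3–2.5 million km²; 30 Holocene and 40 historical localities per species
(inside the observed 10–111 and 5–249 spans); pre-1900 contraction rising
with log10 mass (0.9 per decade) and falling with trophic level (−0.6 per
step, herbivores hit harder early) around a logit-scale base of −2.5; a
weaker, trophic-led post-1900 signal; Brownian residuals (σ = 0.8, λ = 1);
six predictor surfaces as smoothed Gaussian random fields with Temp–Rain
and AET–PET correlations imposed exactly (0.7 and 0.8) by mixing
orthonormalized latents; and per-cell loss log-odds with the canonical
signs (−0.8 elevation, +0.7 HFI, −0.4 rain, +0.3 temperature, +0.3 AET,
−0.4 PET on z-scored predictors). True ranges are concentric ellipses, so
truth areas are exact polygon areas and nesting is exact. A single master
seed drives fixed per-component offsets, keeping stages independently
reproducible.

Deliberately not emulated: taphonomy and dating error, gazetteer noise,
fragmented or shifting (rather than contracting) ranges, spatial
autocorrelation in the cell-level losses beyond what the smooth predictor
fields induce, and any real geography (a schematic China-like border ships
for demos only, clearly labelled synthetic). Passing recovery tests
therefore show the chain is consistent and unbiased *under its own
assumptions* — they do not validate the attachment rule against ranges
whose true shape is far from convex, where the triangle realization will
under-fill.

## Numerical choices, degeneracies, tie-breaks

* Distance ties in the nearest-feature search break deterministically:
  distance, then feature kind (point < polygon < border), then feature id.
* Points exactly on a boundary count as inside (closed-region convention);
  containment tests tolerate the Clipper quantization (~nanometres).
* A locality point coinciding with its anchor contributes nothing and is
  logged; an empty modern baseline (regionally extinct species) is legal —
  the older layers grow from points and border alone.
* A species whose older-period area is zero has undefined proportions and
  is excluded with a warning, never imputed.
* GLM fits use IRLS to 10^-8 (max 100 iterations); complete separation is
  detected heuristically (fitted probabilities pinned at 0/1 with extreme
  coefficients) and flagged.

## Problem sizes used by the test and acceptance runs

The package's own verification uses sizes chosen to exercise every code
path at desk scale: property tests run faunas of 8–16 species on 1500–2000
km borders with 12–20 localities per species; the recovery studies use 200
replicates each (64-tip tree for PGLS coverage; ~900 and ~225 grid cells
for the spatial-model recovery and model-identification checks); the
end-to-end audit reconstructs 30 species from 30 localities per period on
the full 3000-km landscape and compares estimated against true loss
fractions by rank correlation. The published 34-species area table is
re-derived exactly from its printed areas.

## Known limitations

* The attachment-triangle realization of "connect to two nearest features"
  is one defensible reading of a mapping procedure that is underspecified
  in prose; alternatives (e.g. convex hulls over point clusters) would
  reconstruct systematically larger ranges.
* EOO polygons ignore occupancy: a reconstructed range is an outer
  envelope, and area-of-occupancy style measures are deliberately out of
  scope.
* The Human Footprint surface is a current-day composite even when used
  for pre-modern intervals; no temporal correction is attempted.
* The spatial models ignore residual spatial autocorrelation; support for
  closely ranked models should be read accordingly.
* Reading rasters is limited to the plain-text ESRI ASCII grid format.
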