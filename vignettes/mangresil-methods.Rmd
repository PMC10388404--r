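---
title: "Methods: mangrove assessment and coastal exposure in mangresil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mangrove assessment and coastal exposure in mangresil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangresil)
```

`mangresil` implements a multi-sensor mangrove assessment workflow as a
chain of small, separately testable stages. This vignette is the package's
account of the science in each stage: the models, their assumptions, the
parameters that matter and why their defaults are what they are, what the
synthetic scene generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

## 1. Preprocessing

**SAR calibration.** L-band amplitude products ship as digital numbers;
backscatter in decibels is `γ⁰ = 10·log₁₀(DN²) + CF`. The calibration
factor is conventionally quoted as a magnitude of 83 dB for PALSAR-class
products, but applying +83 would put vegetated backscatter near +40 dB,
which is physically implausible (natural surfaces sit roughly between −30
and 0 dB). `dn_to_gamma0()` therefore defaults to `cf = -83` and leaves the
sign configurable. `DN = 0` has no defined logarithm and becomes nodata;
negative digital numbers are rejected as corrupt input rather than
silently squared away.

**Speckle filtering.** SAR speckle is multiplicative salt-and-pepper
noise. No particular filter family is canonical for this workflow, so the
package uses a focal median (`speckle_filter()`, default 3×3): it is
idempotent on constant fields, removes isolated impulses completely,
preserves edges better than a mean filter, and its behaviour is easy to
state and test (it commutes with adding a constant; it strictly reduces
the variance of an i.i.d. field). Windows are odd so the output pixel has
an unambiguous centre; nodata cells are excluded from each window's
median.

**NDVI and masking.** `ndvi()` is the standard normalized band difference,
nodata where both bands are zero. Cloud masking in production systems
means decoding per-sensor QA bitfields; that dialect-specific step is out
of scope, and `apply_mask()` provides the general operation (keep where
mask = 1) that any externally derived mask plugs into.

## 2. Classification protocol

The classifier is a random forest — 100 trees, 5 candidate predictors per
split — applied per pixel to a user-assembled layer stack (typically two
SAR backscatter layers, NDVI and an optical band). The forest itself is
`randomForest`; the package's contribution is the protocol contract around
it:

* **Reproducibility.** Training is seeded (`classifier_config(seed = )`);
  the same stack, samples and seed give bit-identical maps.
* **Tie-breaking.** Prediction uses raw tree votes and picks the maximum
  with ties broken toward the lowest class code, so results do not depend
  on randomized tie resolution.
* **Nodata.** A pixel with any missing feature is nodata in the output;
  training samples on nodata pixels are dropped with a warning.
* **`mtry` capping.** Five predictors per split is the protocol default
  but is capped at the number of available layers (a 4-layer stack trains
  with `mtry = 4`); the cap is recorded in the model metadata.

Samples are drawn stratified by class (allocation proportional to class
pixel counts, largest-remainder rounding) and split into training and
validation sets with `floor(n_total · train_fraction)` training points —
2131 points at an 80/20 split gives 1704 training and 427 validation
points. These are defaults, not constants.

## 3. Accuracy assessment and QADI

From the confusion matrix (rows = classified, columns = reference) the
package reports overall accuracy `100·tr(C)/N`, user's accuracy
(diagonal/row total, the commission view) and producer's accuracy
(diagonal/column total, the omission view). Marginal totals are always
recomputed from the cells — published tables sometimes carry inconsistent
printed totals, and the cells are the primary record.

Total disagreement `D = N − tr(C)` is decomposed into **quantity**
disagreement `Q = ½·Σ_g |row_g − col_g|` (the classes' totals differ) and
**allocation** disagreement `A = D − Q` (right totals, wrong places). The
combined index is

$$\mathrm{QADI} = \sqrt{(A/N)^2 + (Q/N)^2},$$

a [0, 1] quantity with a five-band confidence scale: [0, 0.07) very high
confidence, [0.07, 0.12) high, [0.12, 0.20) moderate, [0.20, 0.30) low,
[0.30, 1] very low. The root-sum-of-squares form is the reading consistent
with a [0, 1] index built from the two disagreement fractions; the
literature's typography for this formula is sometimes garbled, and
published QADI values are not always reproducible from the matrices they
accompany (the 4-class reference matrix used in the test suite decomposes
to Q = 5, A = 9 at N = 1705, giving QADI = 0.00604 under this formula,
where its source prints 0.00529). The suite therefore anchors on the
decomposition identities — `Q + A = N − tr(C)` on fuzzed matrices, QADI
zero exactly for diagonal matrices, invariance under simultaneous class
permutation, `max(A,Q)/N ≤ QADI ≤ (A+Q)/N` — rather than on printed index
values. The kappa coefficient is deliberately not implemented; QADI is
the package's accuracy index precisely because of kappa's well-known
paradoxes.

## 4. Change accounting

`class_areas()` converts pixel counts to hectares
(`count · pixel_size²/10⁴`); `percent_change()` is `100·(a₂ − a₁)/a₁` per
class, `NA` where the base area is zero (relative change is undefined
there, and marking it undefined is safer than reporting infinity).
`transition_table()` cross-tabulates the two epochs in hectares; pixels
nodata in *either* epoch are excluded from the joint table so its
marginals reproduce the per-epoch areas over the jointly valid extent
exactly — a conservation property the tests enforce.

## 5. Canopy height and biomass from a DEM

An interferometric radar DEM over a closed mangrove canopy reads a height
between the ground and the canopy top (near Lorey's height). The package
uses two published scalings: maximum canopy height `H_max = 1.697·H_DEM`,
and the basal-area-weighted height entering the biomass law,
`H_ba = 1.08·H_DEM`. Both factors multiply the **original DEM reading**;
`H_ba` is *not* computed from `H_max`. The two readings cannot be
simultaneously consistent with every published map range (a 12.7-m
maximum height implies `3.25·(1.08·7.48)^1.53 ≈ 79` Mg/ha via the raw-DEM
reading, while biomass maxima near 105 Mg/ha imply `H_ba ≈ 9.7` m — between
`1.08·H_DEM` and `1.697·H_DEM`); the package follows the literal
definition of each factor and documents the tension rather than blending
them. Biomass density is `B = 3.25·H_ba^1.53` Mg/ha, strictly increasing,
with heights below a configurable floor (default 0) clamped before
exponentiation and negative heights rejected.

## 6. Field allometry

Three per-tree models, all in kg with DBH `D` in cm, height `H` in m and
wood density `ρ` in g/cm³:

| model | form | inputs |
|---|---|---|
| Komiyama (pantropical) | `0.251·ρ·D^2.46` | D, ρ |
| Chave (pantropical) | `0.0509·ρ·D²·H` | D, H, ρ |
| Njana (East African mangrove) | `0.353·ρ^1.13·D^2.08·H^0.29` | D, H, ρ |

On a typical small mangrove stem (D = 4.48 cm, H = 6.10 m, ρ = 0.87) they
give 8.74, 5.42 and 11.53 kg — the Chave < Komiyama < Njana ordering the
tests pin down. Wood density comes from an eight-species reference table
(low/middle/high); the default policy applies the conventional global
average of the middle values, 0.87 g/cm³, kept as printed even though the
table's own middle-column mean is 0.8725 — the rounded value is the one in
established use, and the difference (0.3%) is far below allometric model
error. A per-species policy (`species_middle`) is available and falls back
to the default with a warning for unknown species.

Plot aggregation sums per-tree biomass (kg) and normalizes by plot area to
Mg/ha. Stems below 2 m are excluded by default, matching the standard
field protocol of measuring only trees above breast-height reach; the
filter is configurable. Per-plot kilogram sums are reported alongside
Mg/ha because published transect tables sometimes label per-tree kilogram
values as Mg/ha; reporting both keeps either comparison possible.

## 7. Coastal exposure index

Shoreline points every 250 m carry six hazard variables. Each is ranked
1–5; the exposure index is the geometric mean
`EI = (R_geo·R_relief·R_hab·R_wind·R_wave·R_surge)^(1/6)`, symmetric in
its arguments, strictly increasing in each rank, and bounded in [1, 5].

Rank assignment is the genuinely open design point: the originating
framework defers to "user- and model-defined criteria". The package uses
percentile binning at the 20/40/60/80th percentiles of the supplied values
(`rank_variable()`), with a direction flag — relief is ranked
`lower_is_riskier` since low-lying coast floods first — a neutral rank 3
for variables with no variation, and pass-through for variables already
scored 1–5 (e.g. a geomorphology erodibility class). Percentile ranks are
*relative to the supplied shoreline*: they answer "which segments of this
coast are most exposed", not "how exposed is this coast absolutely", which
is the question the with/without-habitat comparison needs.

The habitat scenario sets the habitat rank to 1 where mangrove fronts the
point (fully protective) and 5 in its absence (no protection); both are
configurable, and the without-rank must be ≥ the with-rank, which
guarantees no point's EI decreases when the habitat is removed. Risk
classes are equal-width bins of [1, 5] (very low [1, 1.8) … very high
[4.2, 5]); the originating framework maps classes to ranks but publishes
no EI cut-points, so equal widths are the assumption-free choice.

Wind/wave/surge derivation from met-ocean reanalysis products is out of
scope; per-point values are inputs.

## 8. The synthetic scene

`generate_scene()` builds every pipeline input from a seed:

* **Epoch-1 classes** threshold a smoothed Gaussian latent field (box
  filter, radius 2 px) at the quantiles of the class fractions, so classes
  form contiguous patches — spatial structure a classifier and a speckle
  filter actually encounter — while empirical fractions track the
  specification tightly. Default fractions (water 0.278, mangrove 0.253,
  bare/built-up 0.058, other vegetation 0.411) mirror the 2009 area shares
  of the estuarine study system the defaults emulate.
* **Epoch-2 classes** are drawn per pixel from the transition-matrix row
  of the epoch-1 class. The default matrix retains 83% of mangrove and
  loses the rest to water, bare land and other vegetation, reproducing a
  decade-scale loss of roughly 15–17% net.
* **Band stacks** (SAR VH/VV in dB, NDVI, red reflectance) are Gaussian
  class signatures, noise 1 dB on SAR layers and ~0.08 on index layers,
  separations of several σ between classes.
* **The DEM** is uniform on [3.71, 7.48] m inside the mangrove mask (the
  epoch-1 mangrove extent) and 0 outside — the range whose 1.697-scaled
  envelope is the 6.3–12.7 m maximum-height band reported for West African
  estuarine mangroves.
* **Inventory and shore points**: four 5×5-m plots every 25 m on a 100-m
  transect with landward-decaying stem density (log-normal DBH, height
  roughly linear in DBH, some stems under the 2-m threshold to exercise
  the filter), and shoreline points every 250 m with right-skewed
  (log-normal) wind/wave/surge, a 1–5 geomorphology score and ~60% habitat
  presence.

What it does **not** emulate: radiometric SAR physics (speckle is not
multiplicative gamma noise), mixed pixels and class gradients, terrain and
geometric distortion, cloud structure, species-level height allometry, and
met-ocean forcing. Passing tests therefore demonstrate the pipeline's
correctness and internal consistency — not classifier performance on real
imagery, where separability is far lower than the synthetic signatures
provide.

## 9. Problem sizes, tolerances and degenerate inputs

The test suite and the end-to-end run use scenes of 40–150 px per side
and 300–2131 sample points — large enough for the multinomial/binomial 3σ
convergence checks and classifier accuracy ≥ 95% with headroom, small
enough that the whole suite runs in seconds. Closed-form expectations
(calibration arithmetic, EI closed forms) are asserted at 1e-9 or exact;
stochastic properties use 3–4σ bounds derived from the generating
distributions, never ad-hoc tolerances. Percentages are presented at one
decimal (conventional half-up rounding, which is how the reference tables
round exact .x5 cases), QADI at five decimals.

Degenerate inputs are defined errors, not silent results: empty label
vectors, single-class training sets, even filter windows, negative DBH or
DEM heights, all-nodata masks, zero-length shorelines, out-of-range
exposure indices. Zero-denominator cases inside otherwise valid inputs
(`DN = 0`, `NIR + Red = 0`, zero base area, zero-pixel classes in
stratification) become nodata/`NA` with a warning where recoverable.

## 10. Known limitations

* Raster I/O is plain-text Esri ASCII grid — interoperable with GDAL/QGIS
  but uncompressed and single-band per file; no CRS metadata is carried.
* The percentile ranking makes EI distributions relative to the analysed
  shoreline; comparing two different coastlines requires user-supplied
  absolute break criteria.
* The DEM height scalings are empirical regressions from tall closed
  canopies; both are biased for short, sparse or disturbed stands.
* Exposure percentages depend on the rank-assignment criteria; only the
  ordering properties (habitat removal never decreases EI; high-risk share
  non-decreasing) are assumption-free, and those are what the tests
  assert.
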