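# mangresil

Mangrove ecosystems shield tropical coasts from wind, waves and surge, yet
they are hard to monitor: persistent cloud cover defeats purely optical
satellite mapping, and field campaigns cover only transects. `mangresil` is
an R package for the combined assessment workflow that coastal-resilience
studies use in practice — multi-sensor land-cover mapping with a rigorous
accuracy index, change accounting, structure-from-elevation biomass
estimation, field allometry, and an exposure index that quantifies what the
mangrove is worth as a natural defence. A synthetic scene generator with
controlled statistical structure stands in for the satellite, DEM and field
data, so the whole pipeline is testable offline and end to end.

## What it computes

**Classification accuracy and QADI.** Land cover is classified per pixel by
a random forest (default 100 trees, 5 predictors per split) into water,
mangrove, bare/built-up and other vegetation. Accuracy is assessed from the
confusion matrix `C` (rows = classified, columns = reference, `N` points):
overall accuracy `OA = 100 · tr(C)/N`, per-class user's/producer's accuracy,
and the quantity–allocation disagreement index

```
Q = ½ Σ_g |row_g − col_g|,   A = (N − tr C) − Q,
QADI = √((A/N)² + (Q/N)²)
```

with a five-step confidence scale (QADI < 0.07 ⇒ "Very high confidence").

**Change accounting.** Class areas in hectares
(`count · pixel_size²/10⁴`), signed percent change per class, and the k×k
class-transition cross-tabulation whose marginals reproduce the per-epoch
areas exactly.

**Canopy height and biomass from a DEM.** Over a closed canopy an
SRTM-class DEM reads between ground and canopy top, so maximum height is
`H_max = 1.697 · H_DEM` and the biomass-relevant basal-area-weighted height
is `H_ba ≈ 1.08 · H_DEM`; aboveground biomass density follows the power law
`B = 3.25 · H_ba^1.53` (Mg/ha).

**Field allometry.** Per-tree biomass (kg) from DBH `D` (cm), height `H`
(m) and wood density `ρ` (g/cm³) under three models —
Komiyama `0.251·ρ·D^2.46`, Chave `0.0509·ρ·D²·H`, Njana
`0.353·ρ^1.13·D^2.08·H^0.29` — with a wood-density table and plot/transect
aggregation to Mg/ha.

**Coastal exposure.** At shoreline points every 250 m, six hazard variables
(geomorphology, relief, habitats, wind, wave, surge) are ranked 1–5 and
combined as the geometric mean `EI = (R₁⋯R₆)^(1/6)`. Recomputing EI with
the habitat rank at its protective value versus its absent value measures
the mangrove's defensive contribution.

## Worked example

```r
library(mangresil)

## accuracy assessment of a published 4-class error matrix (N = 1705)
cm <- confusion_matrix(rbind(
  c(81,   0,  0,   0),
  c( 0, 642,  1,   4),
  c( 0,   0, 32,   0),
  c( 0,   9,  0, 936)),
  c("water", "mangrove", "bare_builtup", "other_vegetation"))
accuracy_report(cm)
#> Overall accuracy: 99.2% (N = 1705)
#> Disagreement: Q = 5, A = 9, D = 14
#> QADI = 0.00604 (Very high confidence)
#>              class users_accuracy producers_accuracy
#> 1            water         100.00             100.00
#> 2         mangrove          99.23              98.62
#> 3     bare_builtup         100.00              96.97
#> 4 other_vegetation          99.05              99.57
```

1691 of 1705 points sit on the diagonal; the 14 disagreeing points split
into 5 of quantity (class totals differ) and 9 of allocation, and the QADI
of 0.006 lands far inside the very-high-confidence band.

```r
## a decade of mangrove loss, from area tables
a1 <- data.frame(class = "mangrove", code = 1, area_ha = 1613)
a2 <- data.frame(class = "mangrove", code = 1, area_ha = 1340)
percent_change(a1, a2)$percent_change
#> [1] -16.92498        # a 16.9% loss

## one inventoried tree, three allometric models (kg per tree)
c(agb_komiyama(4.48, 0.87),
  agb_chave(4.48, 6.10, 0.87),
  agb_njana(4.48, 6.10, 0.87))
#> [1]  8.736488  5.421543 11.530161
```

The full pipeline on a synthetic scene — generation, speckle filtering,
two-epoch classification, accuracy, change, canopy/biomass, allometry,
exposure scenarios:

```r
res <- run_pipeline(run_config(seed = 1), quiet = TRUE)
res$manifest$accuracy$t1$overall    #> 98.4   (% validation accuracy)
res$manifest$accuracy$t1$qadi       #> 0.0117 ("Very high confidence")
res$manifest$percent_change["mangrove"]  #> -15.2  (% over the decade)
res$manifest$height_m               #> min 6.30, max 12.69 m
res$exposure$summary
#>   risk_class with_habitat_pct without_habitat_pct
#> 1   very low         15.38462             0.00000
#> 2        low         61.53846            38.46154
#> 3   moderate         23.07692            38.46154
#> 4       high          0.00000            23.07692
#> 5  very high          0.00000             0.00000
```

With the mangrove present no shoreline point exceeds moderate risk; remove
it and 23% of points move into the high-risk class — the distribution shift
is the habitat's protective value.

A command-line wrapper over the same functions lives at
`inst/cli/mangresil.R` (subcommands `simulate`, `preprocess`, `ndvi`,
`assess`, `change`, `canopy`, `allometry`, `vulnerability`, `run-all`).

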