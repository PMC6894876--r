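# grassocd

Multi-method estimation of topsoil (0–30 cm) soil organic carbon
density (SOCD) and stocks for steppe and meadow grassland.

Regional soil-carbon accounting on high-cold grasslands typically mixes
three data sources: legacy soil-survey profiles (bulk density, SOC or
SOM per layer), empirical pedotransfer models relating bulk density to
SOC, and satellite vegetation indices (NDVI) regressed against SOCD.
`grassocd` implements that whole workflow as composable, tested R
functions, for ecosystem ecologists and carbon-accounting analysts who
need the pieces to be auditable rather than buried in GIS toolchains.

## The models at the core

**Pedotransfer inversion.** Four empirical bulk-density models of the
form BD = c + a·exp(−b·SOC) (BD in g·cm⁻³, SOC in g·kg⁻¹):

| model | equation |
|---|---|
| 1 | BD = 0.3 + 1.28·exp(−0.01724·SOC) |
| 2 | BD = 1.515·exp(−0.102·SOC) |
| 3 | BD = 0.9955 + 0.5427·exp(−0.077·SOC) |
| 4 | BD = 1.4055·exp(−0.1039·SOC) |

Each is inverted in closed form, SOC = −ln((BD − c)/a)/b, valid on
BD ∈ (c, a + c]; out-of-domain records are flagged, never dropped.

**Layered SOCD integral.** SOCD = Σᵢ Tᵢ·BDᵢ·SOCᵢ·(1 − Cᵢ/100)/100 over
the layer scheme 0–9.1, 9.1–16.6, 16.6–30 cm (Tᵢ thickness in cm, Cᵢ
the % gravel fraction > 2 mm); the /100 resolves the units to
kg C·m⁻² exactly.

**NDVI retrieval.** Annual maximum-value composites, optional block
aggregation (1 km → 10 km), then per-type linear retrieval:
SOCD_steppe = 20.201·NDVI − 0.9206, SOCD_meadow = 17.846·NDVI + 0.0155,
with saturation flagging at NDVI ≥ 0.8.

**Trend analysis.** Per pixel: OLS slope of SOCD on serial year,
Mann–Kendall S/Z with tie-corrected variance and the ±1.96 decision
rule, Theil–Sen slope, and the five-level slope classification
(breaks at −0.1, −0.01, 0.01, 0.1 per year, half-open).

**Stocks & drivers.** Zonal storage Σ SOCD·cell-area in 10¹⁰ kg by
grassland type; IDW / ordinary-kriging point interpolation; Pearson
correlation screening of SOCD against biomass, soil moisture,
temperature, conductivity and elevation with p < 0.05 / p < 0.01 flags.

A seeded synthetic-data generator (`synthetic_spec()` + `gen_*()`)
emulates all inputs with known ground truth, so every stage is testable
offline.

## Worked example

```r
library(grassocd)

## invert bulk density to SOC with model 1
m1 <- ptf_models()[["1"]]
soc <- invert_soc(m1, c(1.05, 0.95))
round(as.numeric(soc), 2)
#> [1] 31.01 39.31     # g C per kg soil
attr(soc, "flag")
#> [1] "ok" "ok"

## 0-30 cm SOCD of a two-layer profile, resliced onto the scheme
p <- soil_profile("QTP-001", grassland_type = "meadow",
  layers = data.frame(top = c(0, 15), bottom = c(15, 30),
                      bd = c(1.05, 1.25), soc = c(38, 16),
                      gravel = c(5, 12)))
profile_socd(p)
#> $layers
#>   layer  top bottom     socd
#> 1     1  0.0    9.1 3.449355
#> 2     2  9.1   16.6 2.552247
#> 3     3 16.6   30.0 2.358400
#> $total
#> [1] 8.360002            # kg C per m^2, sum of the layers exactly

## full pipeline on the synthetic stated world (50x50 x 10 km,
## 2000-2015, 200 profiles, 59 plot surveys)
res <- run_socd_pipeline(synthetic_spec(seed = 42))
res$regional
#>   grassland_type  slope    sen mk_z mk_significance
#> 1         steppe 0.0211 0.0215 5.36    sig_increase
#> 2         meadow 0.0645 0.0643 5.36    sig_increase
res$trend$class_area
#>                      class steppe meadow total
#> 1     significant decrease   0.00   0.00  0.00
#> 2 non-significant decrease  14.08   0.72  7.40
#> 3      nearly unchangeable  21.68   3.52 12.60
#> 4 non-significant increase  63.60  82.48 73.04
#> 5     significant increase   0.64  13.28  6.96
subset(res$storage, method == "ndvi")
#>   method grassland_type layer n_cells area_km2 mean_socd storage_1e10kg
#>     ndvi         steppe total    1250   125000     3.250          40.62
#>     ndvi         meadow total    1250   125000     8.222         102.78
#>     ndvi            all total    2500   250000     5.736         143.40
round(res$correlations$r[1, ], 2)
#>  socd biomass moisture temperature conductivity elevation
#>  1.00    0.56     0.48       -0.30        -0.43     -0.25
```

Reading the output: both grassland types show a significant upward
SOCD trend (Z = 5.36 > 1.96), the meadow rising ~3× faster
(0.065 vs 0.021 kg C·m⁻²·yr⁻¹); most pixels fall in the
"non-significant increase" slope class (0.01 ≤ slope < 0.1); meadow
stores ~2.5× the steppe's carbon over equal area; and SOCD correlates
positively with biomass and moisture, negatively with temperature,
conductivity and elevation — all by construction of the seeded
synthetic world, which is the point: the pipeline demonstrably
recovers the structure that was planted.

## Command line

```sh
inst/cli/grassocd simulate --seed 1 --out fixture/
inst/cli/grassocd trend --stack fixture/years/ --mask fixture/mask.asc
inst/cli/grassocd correlate --surveys fixture/surveys.csv
```

Rasters are exchanged as plain-text ESRI ASCII grids; tables as CSV.
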