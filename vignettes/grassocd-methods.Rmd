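---
title: "Methods: multi-method topsoil SOCD estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-method topsoil SOCD estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grassocd)
```

## The estimation problem

Topsoil organic carbon density (SOCD, kg C·m⁻² over 0–30 cm) on
high-cold steppe and meadow grassland can be estimated three ways, each
with different failure modes:

1. **directly**, from measured per-layer SOC, bulk density (BD) and
   gravel content of soil profiles;
2. **by pedotransfer inversion**, when a legacy survey recorded BD but
   not SOC: an empirical BD(SOC) model is inverted per layer;
3. **by satellite retrieval**, regressing SOCD on annual NDVI
   separately per grassland type, which adds spatial and temporal
   coverage the sparse profiles cannot give.

`grassocd` implements all three, the downstream trend and stock
accounting, and a correlation screen of environmental drivers, so that
the methods can be compared on one dataset. Because the original
continental-scale inputs (a national soil survey, 16 years of MODIS
composites) are not redistributable, the package ships a seeded
generator that emulates them with known ground truth; every claim the
test suite makes is a claim about recovering that truth.

## Pedotransfer models and their inversion

The supported form is BD = c + a·exp(−b·SOC). Four published
coefficient sets are frozen in `ptf_models()`; user models of either
form (`c = 0` or `c > 0`) are accepted via `ptf_model()` and a CSV
registry. The inverse is closed-form, SOC = −ln((BD − c)/a)/b, and is
only defined on BD ∈ (c, a + c]:

* **BD > a + c** would demand negative SOC. Policy-controlled: the
  default flags the record missing (`above_intercept`); `clamp_zero`
  sets SOC = 0, for workflows that must keep every profile.
* **BD ≤ c** has no finite preimage (`below_asymptote`), always
  missing. Flags travel with the records; nothing is dropped silently.

The analytic inverse is verified against bisection root-finding of the
forward model, and the round trip forward(inverse(bd)) is exact to
1e−9 relative across all four domains.

### The Model-3 anomaly, and how we test "qualitative"

With the printed coefficients, Model 3 (asymptote c = 0.9955 g·cm⁻³)
behaves structurally differently below BD ≈ 1.1: its inverse diverges
to +∞ as BD approaches 0.9955 from above and is undefined below it,
while Models 1/2/4 stay finite over the whole physically common BD
range. Formalizing "Model 3 departs from the other three by more than
their mutual spread" needed care, because a naive pointwise reading is
false for the printed coefficients: Model 1's inverse is itself far
from Models 2/4 at low BD (at BD = 1.0: M1 ≈ 35, M2 ≈ 4.1,
M4 ≈ 3.3 g·kg⁻¹), and Model 3 crosses Model 1 near BD ≈ 1.04. The
acceptance test therefore asserts an aggregate over the common-domain
grid BD ∈ (0.9965, 1.1): the mean distance from Model 3 to its nearest
neighbour among the trio must exceed the trio's mean closest-pair
distance (measured ≈ 6.6 vs ≈ 0.79 g·kg⁻¹), and Model 3's
near-asymptote values must exceed everything the other models produce
on the grid. Both formalizations were fixed from the model algebra
before the test was frozen.

## The SOCD integral and its units

SOCD = Σᵢ Tᵢ·BDᵢ·SOCᵢ·(1 − Cᵢ/100)/100 with Tᵢ in cm, BDᵢ in g·cm⁻³,
SOCᵢ in g·kg⁻¹ and Cᵢ the percent gravel (> 2 mm) excluded from the
fine-earth stock. Dimensional analysis — 1 cm = 10⁻² m,
1 g·cm⁻³ = 10³ kg·m⁻³, 1 g·kg⁻¹ = 10⁻³ kg C per kg soil — shows the
/100 is exactly the unit resolution, so the canonical output unit is
kg C·m⁻². (Source tables for this family of studies sometimes print
"kg·cm⁻²" next to values of ~5–6, which is treated here as a
typographical unit error; no display-unit conversion is applied.)

Arbitrary profile layering is resliced onto the fixed scheme
0–9.1 / 9.1–16.6 / 16.6–30 cm by thickness-weighted averaging of the
overlapping source layers. For piecewise-constant properties this
conserves mass exactly; profiles that do not reach 30 cm are excluded
from group statistics and surfaced in a QC report rather than erroring
a whole batch. Gravel defaults to 0 when a survey omits it — common in
1:1M survey summaries — and the omission is flagged on the profile.

The SOM route inverts the printed relation SOM = SOC × 0.58 by default
(`as_printed`, SOC = SOM/0.58). Because that printed direction
contradicts the conventional van Bemmelen relation SOM = 1.724·SOC,
the conventional direction (`van_bemmelen`, SOC = 0.58·SOM) is also
implemented; the choice is an explicit argument and rides the method
tag through all downstream tables.

## NDVI compositing, aggregation and retrieval

`mvc_annual()` is the per-pixel maximum over sub-annual composites,
nodata-ignoring: the standard suppression of clouds and large solar
zenith angles. `aggregate_blocks()` does non-overlapping block means
(e.g. factor 10 for 1 km → 10 km), averaging whatever cells a partial
edge block has. MVC-then-aggregate is the default order, matching the
usual processing narrative; both functions are exposed so the order
can be swapped.

`ndvi_to_socd()` applies the per-type linear retrievals (steppe
20.201·NDVI − 0.9206; meadow 17.846·NDVI + 0.0155, both kg C·m⁻² over
0–30 cm); pixels outside the two classes are nodata, and class
boundaries never mix equations. Two flags are produced rather than
silently altered values: negative predictions (steppe NDVI < ~0.0456)
are clamped to 0 with a flag (clamping defaults on because negative
SOCD is unphysical), and NDVI ≥ 0.8 sets a saturation flag — dense
meadow canopies saturate NDVI, biasing retrieval low, and no published
correction exists, so the package only marks the pixels.

## Trend analysis

Per pixel over the annual SOCD series (serial year i = 1..n; n always
taken from the supplied stack, never hard-coded):

* **OLS slope** in the textbook closed form
  (n·Σi·xᵢ − Σi·Σxᵢ)/(n·Σi² − (Σi)²), missing years dropped pairwise;
* **Mann–Kendall**: S = Σ_{i<j} sign(xⱼ − xᵢ); variance with tie
  correction [n(n−1)(2n+5) − Σₜ t(t−1)(2t+5)]/18 (ties are standard
  practice even where source descriptions are silent); continuity-
  corrected Z; significance three-way at ±1.96;
* **Sen slope**: median pairwise slope, shift-invariant and sign-
  consistent with S;
* **five-level classification** of the OLS slope with half-open breaks
  exactly as printed: (−∞,−0.1), [−0.1,−0.01), [−0.01,0.01),
  [0.01,0.1), [0.1,∞). The "significant"/"non-significant" class
  labels are slope-magnitude names only, deliberately decoupled from
  the Mann–Kendall Z, which is reported per pixel alongside.

Pixels with fewer than 3 valid years are nodata and excluded from the
class-area percentages, which sum to 100 per stratum by construction.

### Why the type-I acceptance test uses 30-year series

The Mann–Kendall statistic is discrete, so the attained level of the
|Z| > 1.96 rule depends on n. Exact enumeration of the null
distribution of S gives an attained two-sided level of 0.0413 at
n = 16 (the emulated 2000–2015 span) and 0.0491 at n = 30. A 16-year
series can therefore sit below a 0.05 ± 0.01 acceptance band through
no fault of the implementation. The type-I criterion is accordingly
evaluated at series length 30 — the asymptotic regime the nominal
level refers to — with 4,000 pixels (Monte-Carlo s.e. ≈ 0.0035). This
was decided from the enumeration before the test was frozen, not tuned
afterwards.

## Stocks

`zonal_storage()` is exact bookkeeping: Σ SOCD × cell-area over the
valid pixels of each type, reported in 10¹⁰ kg; nodata pixels leave
both the storage and the area. Pixel area defaults to cellsize²
(projected coordinates assumed; no spherical-area correction — a
documented limitation for geographic grids). Profile-based methods
get storage as group-mean SOCD × type area, with per-layer rows; the
NDVI method is total-only, because its regressions predict the whole
0–30 cm stock and any per-layer split would be invented.

Point-to-grid interpolation offers IDW (default: deterministic,
parameter-light, power 2, 12 neighbours) and ordinary kriging with an
isotropic exponential variogram γ(h) = nugget + psill·(1 − e^{−h/range})
— supplied or moment-fit from binned empirical semivariances. Kriging
honours γ(0) = 0, so both methods interpolate exactly at data sites;
a degenerate variogram falls back to IDW with a warning rather than
failing the run. Kriging is optional rather than default because no
variogram is published for the emulated survey.

## Correlation screening

`correlation_matrix()` computes all pairwise Pearson r with pairwise
deletion (per-pair n reported) and flags two-sided t-test significance
(t = r·√((n−2)/(1−r²)), df = n−2) at 0.05 and 0.01. |r| = 1 is flagged
p < 0.01 by convention since the statistic diverges. No
multiple-testing correction is applied by default — matching the
screening style this reproduces — but `adjust` exposes the `p.adjust`
family for users who want it.

## The synthetic stated world

Defaults of `synthetic_spec()` are fixed once and are the conditions
the tests and acceptance criteria run under:

| parameter | default | why |
|---|---|---|
| grid | 50 × 50 cells of 10 km | the aggregated working resolution; seconds-scale tests |
| years | 2000–2015 (16) | the emulated MODIS span |
| mask | west half steppe, east half meadow | the real gradient is steppe-NW → meadow-SE; split halves keep areas exactly checkable |
| NDVI intercepts | steppe N(0.20, 0.05), meadow N(0.43, 0.08) | back-solved through the retrieval equations from regional SOCD levels ≈ 3.2 (steppe) and ≈ 7.75 (meadow) kg C·m⁻² |
| NDVI slopes | steppe N(0.0010, 0.0010), meadow N(0.0036, 0.0015) yr⁻¹ | back-solved from regional SOCD rates ≈ 0.021 / 0.065 kg C·m⁻²·yr⁻¹ |
| NDVI noise | Gaussian, σ = 0.02, clipped to [0, 1] | interannual scatter of annual MVC composites; a stand-in, no published error model |
| profiles | 200; SOC lognormal, medians 30/20/10 g·kg⁻¹ by layer, σ_log 0.4; BD = model 1 forward + N(0, 0.05), truncated in-domain; gravel U(0, 20)% | right-skewed SOC declining with depth, realistic BD scatter, survey-typical gravel |
| surveys | 59 plots; correlation targets with SOCD–biomass 0.60, SOCD–moisture 0.55, SOCD–temperature −0.30, SOCD–conductivity −0.35, SOCD–elevation −0.25, temperature–conductivity 0.45, moisture–conductivity −0.40, temperature–elevation −0.50 | the emulated field campaign's sample size; driver signs as reported for this system |

Reproducibility: one root seed; each generator draws from a derived
substream, so regenerating one input never perturbs another, and
identical spec + seed gives byte-identical text outputs (asserted by
the determinism acceptance test).

**What a green test does not establish.** The generator plants linear
trends with independent Gaussian noise and no spatial autocorrelation,
a geometrically trivial mask, no MODIS QA artifacts, no clouds, and
profiles whose BD–SOC relation really follows the generating model.
Green tests therefore establish that the algorithms recover known
structure under their own assumptions — not that any particular
regional carbon number is right, and not robustness to autocorrelated
noise, which the trend test is known to be sensitive to (pre-whitened
variants are out of scope).

## Numerical choices and degenerate inputs

* Classification breaks are half-open exactly as printed; −0.1 falls
  in "non-significant decrease", 0.1 in "significant increase".
* The inverse at the intercept BD = a + c returns exactly 0 (a −0
  guard absorbs floating-point sign).
* `ols_slope` returns NA for < 2 distinct time points; `mann_kendall`
  errors below 3 values (raster wrapper converts to nodata);
  all-equal series give S = 0, Z = 0, "none".
* Zero-variance vectors make Pearson r undefined (NA + warning), and
  a constant column flags its pairs `undefined` in the matrix.
* Interpolation treats a site within 1e−9 map units of a cell centre
  as coincident and returns the site value (exactness).
* Rasters travel as ESRI ASCII grids (plain text) because the target
  environment ships no GeoTIFF reader; nodata sentinel −9999, 10
  significant digits, which round-trips the double values used here.

## Known limitations

No reprojection or geographic-area weighting; no MODIS HDF/QA
ingestion (MVC is the only artifact suppression, as in the emulated
workflow); no EVI variant for the saturation problem; no uncertainty
propagation through the pedotransfer step; no pre-whitening of the
Mann–Kendall test; kriging is global (all points in one system), fine
for hundreds of sites but not tens of thousands.
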