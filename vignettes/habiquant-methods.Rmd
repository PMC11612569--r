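---
title: "Models and methods in habiquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in habiquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habiquant)
```

habiquant implements a habitat-quality assessment pipeline for
categorical land-use rasters: a threat-decay degradation and quality
model, land-use transition accounting, global and local spatial
statistics, and a latent-variable path model of quality drivers. This
vignette documents the models, the defaults and why they were chosen,
the numerical decisions, and what the synthetic-data tests do and do not
establish.

## The habitat-quality model

Every cell $x$ carries a land-use class $j(x)$. The legend gives each
class a habitat suitability $H_j \in [0,1]$ and a sensitivity
$S_{jr} \in [0,1]$ to each threat factor $r$; the threat table gives each
threat its source classes, maximum influence distance $d_{r,max}$ (km),
relative weight $\omega_r$ and decay type. Degradation accumulates over
all source cells $y$ of all threats:

$$D_x = \sum_r \sum_{y \in Y_r} \frac{\omega_r}{\sum_r \omega_r}\,
  i_r(d_{xy})\, \beta_x\, S_{j(x),r},$$

with $i_r(d) = \max(0, 1 - d/d_{r,max})$ for linear decay and
$i_r(d) = \exp(-2.99\, d/d_{r,max})$ for exponential decay, both
truncated to zero strictly beyond $d_{r,max}$, and distances measured
center-to-center in km. Quality follows from a saturating penalty:

$$Q_x = H_{j(x)} \left(1 - \frac{D_x^z}{D_x^z + k^z}\right).$$

Decisions worth stating explicitly:

* **The exponential constant.** The kernel is
  $\exp(-2.99\, d/d_{r,max})$: at $d = d_{r,max}$ the impact has fallen
  to $e^{-2.99} \approx 0.05$, which is what makes the exponential form
  the analogue of the linear one. This is the dimensionally consistent
  reading of the decay specification, and the form used by the standard
  habitat-quality tooling.
* **$z$ and $k$.** Neither is dictated by the data; the defaults are the
  convention of that tooling, $z = 2.5$ and $k = 0.5$. Because $D$ is an
  unnormalized sum over source cells, its scale depends on source
  density, so `hq_config(k = "half_max")` is offered as the common
  alternative calibration (quality halves at half the maximum observed
  degradation). Neither choice is asserted as "the" published
  calibration; both are exposed.
* **No normalization by source count.** $D$ sums over source cells as
  the formula is written; $k$ absorbs the scale. Rescaling all
  $\omega_r$ by a positive constant leaves $D$ unchanged (weights enter
  normalized), and this is tested.
* **Self-threatening classes.** A source cell whose own class is
  sensitive to its threat (arable land, saline-alkali land) receives
  that threat at distance zero, $i = 1$: the model places no
  self-exclusion, and the packaged legend intentionally contains such
  classes.
* **Accessibility.** $\beta_x = 1$ by default — no accessibility layer
  is invented — but a grid can be supplied.
* **Grades.** The five grades use left-closed bins $[0,0.2), \dots,
  [0.8,1]$ with 1.0 in "highest". Open-interval grade notation leaves
  the boundaries ambiguous; left-closed binning is total and
  deterministic, and the boundary case 0.2 → "lower" is pinned by a
  test.
* **Change maps.** "Unchanged" is $|\Delta Q| \le$ `eps` with
  `eps = 0.01` by default: one quality unit at the model's two-decimal
  reporting precision. No published value defines "unchanged"; this is
  the package's choice, stated once here.

The kernel implementation (shift-and-accumulate over integer cell
offsets) is verified against a brute-force quadruple loop over
(cell, source, threat) to $10^{-12}$ on small random landscapes.

## Transition accounting

Transition matrices count cells jointly valid at both dates; cells that
are nodata at either date are excluded entirely rather than assigned a
pseudo-class, so row sums equal first-date class areas and column sums
second-date areas (tested as a conservation law). Conversion rates are
row-normalized percentages — "17% of paddy became dry farmland" reads off
a row.

## Spatial statistics

Moran's I uses queen contiguity, row-standardized, by default; Gi* uses
binary queen weights with the focal cell included. The published analyses
this package mirrors name neither the contiguity scheme nor the distance
band of their tooling, so the defaults here are the most common ones and
are stated rather than asserted as the original choices. Nodata cells
are removed from the weights graph entirely, which avoids spurious
zero-weight neighbors. The Moran z-score uses the
randomization-assumption variance (it matches `ape::Moran.I` in the
tests); Gi* z-scores are cut at the fixed normal quantiles 1.645, 1.960,
2.576 into three hotspot and three coldspot confidence tiers with no
multiple-testing correction — that is the classification semantics of
the standard hot-spot tooling, reproduced deliberately.

## The driver path model

The structural equation model combines a measurement part
$Y = \Lambda_y \eta + \epsilon$ (three latents, two indicators each:
Topography ← elevation, slope; Climate ← precipitation, temperature;
HumanDisturbance ← nightlight, population density) with a structural part
$\eta = B\eta + \Gamma\xi + \zeta$ over the latents and the observed
NDVI (mediator) and HQ (terminal response). Estimation choices:

* **Transform first.** Raster-derived variables are passed through a
  rank-based inverse-normal transform then z-standardized
  (`rank_normalize()`). This is a deterministic stand-in for
  distribution-family normalization (Johnson-type selection); it serves
  the same purpose — meeting the normality assumption of ML — without a
  family-selection step.
* **ML on the covariance.** The model is held in RAM form and the ML
  discrepancy $F = \log|\Sigma(\theta)| + tr(S\Sigma^{-1}) - \log|S| - p$
  is minimized by BFGS (relative tolerance $10^{-10}$), variances on the
  log scale to keep them positive, first loading per latent fixed to 1
  for identification, up to 5 seeded jittered restarts. Standardized
  coefficients are derived from the implied variances of all variables.
* **Fit indices.** Conventional definitions: CFI against the
  independence baseline, GFI as $1 - tr[(\Sigma^{-1}(S-\Sigma))^2] /
  tr[(\Sigma^{-1}S)^2]$, RMSEA from $(\chi^2 - df)/(df\,(n-1))$, SRMR on
  the correlation metric. Gates CFI > 0.90, GFI > 0.90, RMSEA < 0.06,
  SRMR < 0.05.
* **Sampling.** Model input is a seeded uniform sample of jointly valid
  cells (default 10,000); the sample size is explicit rather than
  implicit in the raster size.
* **Effects.** Direct = the driver → response edge; each indirect
  contribution = the product of coefficients along one simple directed
  path (the graph is required acyclic); total = their sum. An
  independent computation, $(I-B)^{-1} - I$, must agree to $10^{-12}$.

The packaged per-year Songnen path tables (`songnen_paths()`) carry the
published standardized edge coefficients where individual edges were
published, and solve the unpublished mediator edges from the published
per-channel indirect products; where only the product is available the
split across the channel is nominal — it cancels in every path product,
so no decomposition is affected. The `source` column of each table
records which is which. For 2010 the published human-disturbance
indirect term is printed with an ambiguous sign ("0.03" alongside a
total of −0.16 and a direct of −0.13); the table takes it as −0.03,
which is the only reading consistent with the printed total.

## The synthetic world

The landscape generator states one world and keeps it: a plain whose
eastern quarter is a forest belt, whose center is a cropland core
carrying urban and rural patches, and whose west mixes grassland,
saline-alkali land and wetlands. Class budgets default to the packaged
region's composition (dry farmland ≈ 54%, woodland 12%, grassland 8%,
paddy 6%, wetlands 6%, saline 5%, water 4%, urban 3%, rural 1.5%).
Texture comes from thresholding smoothed Gaussian noise added to zonal
affinities, with exact per-class cell counts allocated greedily by
affinity — so requested proportions are met to rounding. Dynamics are
cell-independent Bernoulli conversions per step; the default rates are
one decade of the published cropland-expansion pattern at half the
published two-decade conversion rates (paddy→dry 0.09, woodland→dry
0.025, grassland→dry 0.045, wetland→dry 0.015, paddy→urban 0.01).

Covariates are smooth fields plus class-linked effects: elevation rises
eastward under the forest belt, slope is its local relief, temperature
falls and precipitation rises with elevation, NDVI carries per-class
greenness plus a positive elevation link, nightlight and population
density concentrate over built cells with a negative elevation link. The
built-in links make topography→NDVI positive and
topography→human-disturbance negative by construction, so sign recovery
through the full pipeline is a meaningful test.

What the generator does **not** emulate: realistic geomorphology or
hydrology, climate fields beyond monotone gradients, spatially
autocorrelated measurement error, and — importantly for the SEM — exact
multivariate normality of raster-derived samples. Data sampled from the
synthetic rasters are spatially autocorrelated and only approximately
factor-structured, so the ML chi-square is inflated there and the RMSEA
gate can fail honestly (the `analysis/05` driver prints this). The
parameter-recovery acceptance check therefore uses
`generate_sem_table()`, which draws exactly from a known path model;
passing it establishes that the estimator recovers truth under the
model's assumptions, not that any particular landscape satisfies them.

## Numerical and format notes

Rasters are ESRI ASCII grids (row 0 northernmost, cell size in km
throughout — threat distances are printed in km, and keeping one unit
avoids silent m/km mix-ups); integer grids round-trip bit-exactly,
floats to 15 significant digits. Inputs are assumed to share one grid:
resampling real products onto a common resolution is upstream
preprocessing, out of scope here. Parameter tables are CSV with threat
names tying the legend's sensitivity columns to the threat list, and the
packaged tables reproduce the published six-threat / 21-class
parameterization cell for cell (tested). Degenerate inputs fail loudly:
constant surfaces for either spatial statistic, all-nodata rasters,
all-zero threat weights, non-positive-definite covariance inputs, cyclic
structural graphs.

Pipeline runs (`run_pipeline()`) take a single JSON config with an
explicit seed; identical config and seed give byte-identical outputs,
and each stage failure names its stage. JSON was chosen over YAML
because the package aims for a dependency-light base-R footprint.
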