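---
title: "Spatially weighted landscape composition metrics: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially weighted landscape composition metrics: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landcomp)
```

## The problem

Stream chemistry in small headwater catchments is strongly shaped by the
surrounding land use, but the plain areal percentage of a category
(forest, meadow, ...) treats a cell at the stream bank and a cell on a
remote ridge as equally influential. Spatial weighting schemes correct
this: each raster cell's contribution is discounted by its distance to
the stream and, optionally, amplified by terrain attributes that govern
runoff delivery. `landcomp` implements a suite of thirteen such
*landscape composition metrics* and a comparison pipeline that asks, for
each water-quality parameter (WQP), which weighting scheme explains the
most variance in a single-predictor linear model.

## The metrics

For a catchment of $n$ cells, a land-use category $k$ with indicator
$I_i(k)$, and a per-cell weight $w_i$, every metric is the weighted
percentage

$$\%LU_k \;=\; 100 \cdot \frac{\sum_{i=1}^{n} I_i(k)\, w_i}{\sum_{i=1}^{n} w_i}.$$

The weight is a product of up to three factors:

* a **distance decay** $D_i = (d_i + 1)^{-1}$, where $d_i$ is either the
  Euclidean distance from the cell centre to the nearest stream cell
  ("Euclid" family) or the along-path D8 flow length to the first stream
  cell on the cell's flow path ("Flow" family); the unweighted metric
  sets $D_i = 1$;
* optionally the **slope gradient** $S_i$ in degrees (suffix "-S");
* optionally the **flow accumulation** $A_i$, raw (suffix "-A") or
  log-transformed, $\ln A_i$ (suffix "-logA"), reflecting the
  concentration of overland flow.

`canonicalMetrics()` enumerates the suite — Unweighted, Euclid,
Euclid-S, Euclid-A, Euclid-logA, Euclid-SA, Euclid-SlogA, and the six
Flow analogues — and this order is also the deterministic tie-break used
everywhere downstream.

Percentages are conserved: whenever every weighted cell carries a
category and the denominator is positive, the values over categories sum
to 100 (the test suite asserts this to $10^{-9}$ on hundreds of
synthetic catchments).

### Units and the "+1" offset

Distances enter the decay in **map units (metres)**, not cell counts:
with a 5 m grid the two readings differ, and metres are the natural
interpretation of a distance measured on a georeferenced raster. The
`+1` offset keeps stream cells at weight 1 and makes the decay finite
everywhere. Because the offset is additive on the metre scale, weights
are *not* invariant to the unit choice; the choice is therefore fixed
and documented rather than silent. (Multiplying *all* weights by a
positive constant — e.g. measuring slope in radians instead of degrees —
cancels in the ratio and changes nothing; the tests assert this too.)

## Terrain derivation

All weight layers come from the DEM and the stream mask:

* **Depression filling** uses priority-flood to the exact spill
  elevation, with no epsilon gradient. Cells on the grid edge or
  adjacent to nodata act as exits. The operation is idempotent and
  leaves non-depression cells untouched.
* **D8 flow direction** sends each cell's entire outflow to the
  neighbour with the maximal positive drop per unit distance (cellsize
  for cardinal, cellsize·√2 for diagonal steps). Ties break by the
  fixed scan order E, SE, S, SW, W, NW, N, NE, so results are
  deterministic and oracle-reproducible. Flats (exact after epsilon-free
  filling) are resolved in three deterministic stages: flat cells
  adjacent to nodata drain into it and become outlets; a breadth-first
  pass then points each remaining flat cell toward the nearest
  already-resolved cell of equal elevation; flat regions with no
  internal drainage exit the grid at their border cells. The result is
  acyclic by construction.
* **Flow accumulation is self-inclusive**: $A_i$ counts the cells whose
  path passes through or starts at $i$, so $A_i \ge 1$ everywhere. The
  common GIS convention ($A = 0$ at ridge cells) would send
  $\ln A_i \to -\infty$ and poison the log-accumulation metrics; with
  self-inclusive counting a ridge cell gets $\ln 1 = 0$ and simply
  contributes nothing there. This is the minimal convention under which
  the log metrics are well defined; whether the original ArcGIS
  workflows added a constant instead is not recoverable, so the choice
  is documented as this package's own.
* **Slope** uses Horn's 3×3 third-order finite difference (the ArcGIS
  default), in degrees, on the *raw* DEM; edges are handled by
  replicated padding and a single-cell grid has slope 0.
* **Euclidean distance** is the exact centre-to-centre distance to the
  nearest stream cell (computed with a two-pass exact distance
  transform, verified against an exhaustive pairwise oracle).
* **Flow length** walks the D8 path and sums per-step lengths until the
  first stream cell. A cell whose path exits the grid without meeting
  the stream gets nodata and is excluded from *both* the numerator and
  the denominator of the flow metrics — excluding is preferable to
  inventing a distance, and for catchments delineated from the same DEM
  (as the synthetic generator does, placing the outlet at the
  maximal-accumulation cell) the excluded set is empty by construction.
  Artificial flow paths running parallel to the stream are an inherent
  artefact of single-direction routing; they are reproduced faithfully,
  not corrected, because the comparison between the Euclid and Flow
  families is part of the scientific question. Multiple-flow-direction
  and D-infinity routing are deliberately out of scope.

## Statistical comparison

`olsFit()` fits one ordinary least-squares regression per (WQP, metric,
category) via `stats::lm`, reporting the slope, its standard error, the
two-sided t-test with $n-2$ degrees of freedom, and $R^2$, which for a
single predictor equals the squared Pearson correlation (asserted to
$10^{-12}$). A constant response is a valid degenerate case (slope 0,
$R^2 = 0$); a constant predictor is an error. `compareMetrics()` ranks
the metrics by $R^2$ within each (WQP, category) cell, breaking ties by
the canonical order, and flags models with $p < \alpha$.

Significance uses $\alpha = 0.05$ with **no multiple-testing
correction** by default: the comparison is descriptive, one flag per
fitted model, and the uncorrected flag is what the heat-map style
summaries of this literature show. A Benjamini–Hochberg switch
(`adjust = "BH"`) is available for users who want family-wise control.
Site-by-parameter exclusions (outliers) and wholesale parameter drops
are configuration inputs, not hard-coded site numbers.

## The synthetic generator

The generator exists so the whole pipeline can be exercised and
validated without any field data. Its defaults describe the study
conditions the package targets:

* **37 catchments**, each on its own 120 × 120 grid of **5 m** cells
  (0.36 km² per grid — a deliberately scaled-down version of real
  headwater catchments, which reach tens of km²; grid size trades
  realism for test-suite speed and is configurable).
* **Terrain**: spectrally filtered Gaussian noise (amplitude filter
  $(k + k_0)^{-2.2}$, giving smooth hills) with ~15 m of relief, plus a
  deterministic valley — a 0.03 m/m down-valley tilt eastward and a
  0.05 m/m cross-valley slope toward the central row — so flow converges
  and the maximal-accumulation cell drains most of the grid. Draws whose
  catchment covers less than 30 % of the grid, or whose thirteen metric
  denominators are not all positive, are regenerated from an
  incremented sub-seed with a logged count.
* **Streams**: cells with flow accumulation ≥ 150 (about 0.4 ha of
  contributing area at 5 m resolution, a conventional
  channel-initiation scale); the threshold auto-lowers with a warning
  rather than returning an empty network.
* **Land use**: a Gaussian random field smoothed to a 12-cell
  (60 m) autocorrelation length and thresholded at the quantile that
  makes the forest share of the catchment hit a target drawn uniformly
  from 15–96 %, with meadow as the complement. Two categories only:
  rare categories (croplands, settlements, water bodies) are exactly the
  ones such analyses drop, so the generator does not produce them.
* **Water quality**: `value = β₀ + β₁·%LU + N(0, σ²)`, homoscedastic
  Gaussian noise — the implicit assumption of the downstream linear
  models. By default one parameter is driven by Euclid-S/forest and one
  by Unweighted/forest, each at population $R^2 = 0.6$, mirroring the
  two empirical regimes (proximity/terrain-governed versus
  composition-governed parameters). σ is derived per study set from the
  realized predictor spread via `noiseSdForR2()`.

What the generator does **not** emulate: real hydrochemistry (export
coefficients, in-stream retention), seasonality, heteroscedastic or
non-Gaussian responses, more than two categories, channel networks from
mapped hydrography, and real spatial correlation *between* catchments
(each grid is independent). A passing pipeline on synthetic data
therefore demonstrates algorithmic correctness and statistical
calibration, not field validity of any particular metric.

## Numerical and design notes

* Grids are plain numeric matrices, row 1 = north, `NA` = nodata;
  co-registration (dims, cellsize, origin) is required exactly — no
  resampling is ever attempted.
* Stream cells participate in the sums under their mapped category by
  default; `excludeStream = TRUE` removes them, since analyses that drop
  a "water" category may prefer not to let channel pixels carry a
  terrestrial label.
* Categories absent from a catchment report 0 rather than `NA`, keeping
  tables rectangular.
* A degenerate denominator (e.g. an all-flat catchment under a slope
  metric) is recorded as a per-(catchment, metric) failure and does not
  abort the rest of the table: one pathological catchment should not
  kill a 37-catchment analysis.
* All randomness flows from a single master seed through explicit
  sub-seeds, and repeated pipeline runs on the same manifest are
  byte-identical (asserted in the tests).

## Validation problem sizes

The test suite validates the routing kernels against exhaustive
brute-force oracles on twenty random 10 × 10 DEMs per operation (exact
equality), conservation on a 100-catchment synthetic set, null
calibration of the slope test over 2000 simulated fits at $n = 37$, and
recovery of the generating metric (within 0.05 of the top $R^2$) across
100 replicate 37-catchment study sets. These sizes were chosen so the
whole suite completes in minutes on a single core while keeping the
Monte-Carlo standard errors well inside the asserted tolerances.

## A worked example

```{r example, eval = FALSE}
cfg <- synthConfig(nCatchments = 6)
set <- generateStudySet(cfg, seed = 1)
head(set$metrics)
cmp <- compareMetrics(set$metrics, set$wqp)
cmp$ranking
```

## Known limitations

* Single-flow-direction routing only; flow-length artefacts parallel to
  streams are inherent to SFD8.
* The ESRI ASCII format carries 6 significant digits through
  `writeAsciiGrid()`; round-tripping a study set perturbs metric values
  at the ~10⁻³ percentage-point level.
* `pearsonMatrix()` reports zero-variance metrics as `NA` rows rather
  than dropping them, leaving the decision to the caller.
* The catchment delineation assumes the outlet cell is on the stream;
  delineating at an arbitrary cell is supported but flow lengths may
  then be undefined for part of the mask.
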