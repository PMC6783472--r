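# landcomp

Spatially weighted landscape composition metrics for modelling stream
water quality in headwater catchments.

## The problem

The fraction of a catchment covered by each land-use category is a
classic predictor of stream chemistry, but it treats every raster cell
as equally influential. In practice a meadow cell on the stream bank
matters more than one on a remote ridge, and cells on convergent flow
paths deliver more runoff than cells on divergent ones. `landcomp`
implements thirteen *landscape composition metrics* that weight each
cell's contribution by hydrologically motivated factors, plus the
pipeline to compare them as predictors of water-quality parameters
(WQP). It is aimed at landscape ecologists and freshwater scientists
who want to test which weighting scheme best explains chemistry
observed at catchment outlets — and at method developers who need a
fully synthetic, reproducible test bed for such schemes.

## The metrics

For a catchment of *n* cells, category *k* with indicator *Iᵢ(k)* and
cell weight *wᵢ*, every metric is the weighted percentage

    %LU_k = 100 · Σᵢ Iᵢ(k)·wᵢ / Σᵢ wᵢ

with *wᵢ* the product of up to three factors:

| factor | definition |
|---|---|
| distance decay | `(d + 1)⁻¹`, *d* = Euclidean distance to the stream (**Euclid** family) or D8 flow-path length to the stream (**Flow** family), in metres; the **Unweighted** metric uses 1 |
| slope (`-S`) | slope gradient in degrees (Horn 3×3 estimator) |
| accumulation (`-A`, `-logA`) | D8 flow accumulation, raw or `ln(A)` (self-inclusive, so `A ≥ 1`) |

The canonical suite is Unweighted, Euclid, Euclid-S, Euclid-A,
Euclid-logA, Euclid-SA, Euclid-SlogA, Flow, Flow-S, Flow-A, Flow-logA,
Flow-SA, Flow-SlogA. The comparison stage fits one linear regression
per (WQP, metric, category) and ranks metrics by R².

The package includes the full raster terrain toolchain this needs —
priority-flood depression filling, D8 (SFD8) flow direction with
deterministic flat resolution, flow accumulation, flow length,
watershed delineation, Horn slope, an exact Euclidean distance
transform, and an ESRI ASCII grid reader/writer — and a synthetic
generator producing drainable DEMs, autocorrelated forest/meadow
mosaics, stream networks, catchment masks and WQP tables with a known
generating metric.

## Worked example

A 3×3 plane tilted toward an eastern stream column, with forest in the
western column and meadow elsewhere:

```r
library(landcomp)
dem    <- gridLayer(matrix(c(2,1,0, 2,1,0, 2,1,0), 3, 3, byrow = TRUE), cellsize = 5)
stream <- gridLayer(matrix(c(0,0,1, 0,0,1, 0,0,1), 3, 3, byrow = TRUE), 5)
lu     <- landUseGrid(matrix(c(1,2,2, 1,2,2, 1,2,2), 3, 3, byrow = TRUE),
                      c("1" = "forest", "2" = "meadow"), 5)
tab <- metricSuite(dem, lu, stream, list(toy = gridLayer(matrix(1,3,3), 5)))
subset(tab, metric %in% c("Unweighted", "Euclid"))
#>  catchment_id     metric category   percent
#>           toy Unweighted   forest 33.333333
#>           toy Unweighted   meadow 66.666667
#>           toy     Euclid   forest  7.228916
#>           toy     Euclid   meadow 92.771084
```

Forest covers a third of the cells (Unweighted 33.3 %), but because it
sits furthest from the stream its Euclid-weighted share collapses to
7.23 % — the distance decay gives the two near-stream meadow columns
weights 1/6 and 1 against 1/11 for the forest column.

End to end on synthetic data, where one WQP is generated from the
Euclid-S forest share at population R² = 0.6:

```r
set <- generateStudySet(synthConfig(nCatchments = 6), seed = 1)
cmp <- compareMetrics(set$metrics, set$wqp)
cmp$ranking
#>              wqp category best_metric   best_r2
#>  wqp_composition   forest  Unweighted 0.5491319
#>  wqp_composition   meadow  Unweighted 0.5491319
#>     wqp_proximal   forest  Flow-SlogA 0.9223672
#>     wqp_proximal   meadow  Flow-SlogA 0.9223672
```

The composition-driven parameter is recovered by the Unweighted metric;
the proximity-driven one is won by a near-duplicate of its generating
metric (Euclid-S reaches R² = 0.889 versus 0.922 here — heavily
correlated metrics trade places at small n, which is itself one of the
method's documented behaviours).

A pipeline run (`runPipeline(list(synth = list(), seed = 1), "out/")`)
writes `metrics.csv`, `summary.csv`, per-category correlation matrices,
`regressions.csv`, `ranking.csv` and a machine-readable log. A thin CLI
with subcommands `synth`, `metrics`, `compare` and `run` is installed at
`inst/cli/landcomp.R`.

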