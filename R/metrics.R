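#' Create a metric specification
#'
#' @param name metric label.
#' @param distance `"none"` (unweighted), `"euclid"` or `"flow"`.
#' @param useSlope multiply weights by slope (degrees)?
#' @param accumulation `"none"`, `"raw"` or `"log"` (natural log of the
#'   self-inclusive flow accumulation).
#' @return A [MetricSpec-class].
#' @export
metricSpec <- function(name, distance = c("none", "euclid", "flow"),
                       useSlope = FALSE,
                       accumulation = c("none", "raw", "log")) {
  new("MetricSpec", name = name, distance = match.arg(distance),
      useSlope = isTRUE(useSlope), accumulation = match.arg(accumulation))
}

#' The canonical suite of 13 landscape composition metrics
#'
#' The unweighted areal percentage plus six Euclidean-distance and six
#' flow-length variants: the bare inverse-distance decay, augmented by
#' slope (S), raw flow accumulation (A), log accumulation (logA), and
#' their products (SA, SlogA). The order of this list is the canonical
#' metric order used for table ordering and for breaking ranking ties.
#'
#' @return A named list of 13 [MetricSpec-class] objects.
#' @export
canonicalMetrics <- function() {
  specs <- list(
    metricSpec("Unweighted",   "none"),
    metricSpec("Euclid",       "euclid"),
    metricSpec("Euclid-S",     "euclid", TRUE),
    metricSpec("Euclid-A",     "euclid", FALSE, "raw"),
    metricSpec("Euclid-logA",  "euclid", FALSE, "log"),
    metricSpec("Euclid-SA",    "euclid", TRUE,  "raw"),
    metricSpec("Euclid-SlogA", "euclid", TRUE,  "log"),
    metricSpec("Flow",         "flow"),
    metricSpec("Flow-S",       "flow",   TRUE),
    metricSpec("Flow-A",       "flow",   FALSE, "raw"),
    metricSpec("Flow-logA",    "flow",   FALSE, "log"),
    metricSpec("Flow-SA",      "flow",   TRUE,  "raw"),
    metricSpec("Flow-SlogA",   "flow",   TRUE,  "log"))
  names(specs) <- vapply(specs, function(s) s@name, character(1))
  specs
}

#' Canonical metric names in Table order
#' @return Character vector of the 13 metric names.
#' @export
metricNames <- function() names(canonicalMetrics())

#' Build the per-cell weight grid for one metric
#'
#' The weight of cell i is the product `D_i * S_i^[useSlope] * Aterm_i`
#' with `D_i = 1` (unweighted), `(euclidDist_i + 1)^-1` or
#' `(flowLen_i + 1)^-1` (distances in map units), `S_i` the slope in
#' degrees and `Aterm_i = 1`, `A_i` or `ln(A_i)` for no, raw or log
#' accumulation. Cells outside the mask, or with nodata in any required
#' layer, get nodata.
#'
#' @param spec a [MetricSpec-class].
#' @param euclidDist,flowLen,slope,accum co-registered [GridLayer-class]
#'   layers; only those the spec requires need be non-NULL. `accum` must
#'   be >= 1 where defined (self-inclusive counting).
#' @param mask co-registered [GridLayer-class]; cells with nonzero,
#'   non-NA mask are inside the catchment.
#' @return A co-registered [GridLayer-class] of weights.
#' @export
buildWeightGrid <- function(spec, euclidDist = NULL, flowLen = NULL,
                            slope = NULL, accum = NULL, mask) {
  stopifnot(is(spec, "MetricSpec"), is(mask, "GridLayer"))
  stopIfNotCoregistered(mask, euclidDist, flowLen, slope, accum)
  inside <- !is.na(mask@values) & mask@values != 0
  w <- matrix(NA_real_, nrow(mask@values), ncol(mask@values))
  w[inside] <- 1
  if (spec@distance == "euclid") {
    if (is.null(euclidDist)) stop("metric requires a Euclidean distance layer")
    w <- w / (euclidDist@values + 1)
  } else if (spec@distance == "flow") {
    if (is.null(flowLen)) stop("metric requires a flow-length layer")
    if (all(is.na(flowLen@values[inside])))
      stop("no flow-connected cells")
    w <- w / (flowLen@values + 1)
  }
  if (spec@useSlope) {
    if (is.null(slope)) stop("metric requires a slope layer")
    w <- w * slope@values
  }
  if (spec@accumulation != "none") {
    if (is.null(accum)) stop("metric requires an accumulation layer")
    a <- accum@values
    if (any(a < 1, na.rm = TRUE))
      stop("accumulation must be >= 1 (self-inclusive counting)")
    w <- w * if (spec@accumulation == "raw") a else log(a)
  }
  gridLayer(w, mask@cellsize, mask@xll, mask@yll)
}

#' Weighted land-use composition of one catchment
#'
#' Evaluates, for every category k, the weighted percentage
#' `%LU_k = 100 * sum_i I_i(k) w_i / sum_i w_i`, the sums running over
#' the defined (non-nodata) weight cells. Categories absent from the
#' catchment report 0, so tables stay rectangular. When every weighted
#' cell carries a category the percentages sum to 100 (within 1e-9).
#'
#' @param landuse a [LandUseGrid-class].
#' @param weights a co-registered [GridLayer-class] from
#'   [buildWeightGrid()] (nodata outside the catchment).
#' @return Named numeric vector of percentages, one per category in the
#'   categories map.
#' @examples
#' lu <- landUseGrid(matrix(c(1,2,2, 1,2,2, 1,2,2), 3, 3, byrow = TRUE),
#'                   c("1" = "forest", "2" = "meadow"))
#' w <- gridLayer(matrix(1, 3, 3))
#' composition(lu, w)  # forest 33.33, meadow 66.67
#' @export
composition <- function(landuse, weights) {
  stopifnot(is(landuse, "LandUseGrid"), is(weights, "GridLayer"))
  stopIfNotCoregistered(landuse, weights)
  w <- weights@values
  ok <- !is.na(w)
  denom <- sum(w[ok])
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate weights (zero denominator)")
  codes <- as.integer(names(landuse@categories))
  out <- vapply(codes, function(k) {
    sel <- ok & !is.na(landuse@codes) & landuse@codes == k
    100 * sum(w[sel]) / denom
  }, numeric(1))
  names(out) <- unname(landuse@categories)
  out
}

#' Derive all terrain layers the metrics need
#'
#' Computes, from a DEM and a stream mask, the filled DEM, slope (on the
#' raw DEM), D8 flow direction, self-inclusive flow accumulation,
#' Euclidean distance to the stream and D8 flow-path length to the
#' stream, all co-registered.
#'
#' @param dem a [GridLayer-class] elevation raster.
#' @param streamMask a co-registered [GridLayer-class], nonzero on
#'   stream cells.
#' @return A named list of layers: `filled`, `slope`, `dirs`, `accum`,
#'   `edist`, `flen`.
#' @export
terrainLayers <- function(dem, streamMask) {
  stopIfNotCoregistered(dem, streamMask)
  filled <- fillDepressions(dem)
  dirs <- d8FlowDirection(filled)
  list(filled = filled, slope = slopeGrid(dem), dirs = dirs,
       accum = flowAccumulation(dirs),
       edist = euclideanDistanceToStream(streamMask),
       flen = flowLengthToStream(dirs, streamMask))
}

#' Compute all landscape composition metrics for a set of catchments
#'
#' Derives the terrain layers once (fill, slope on the raw DEM, D8
#' direction, accumulation, Euclidean distance and flow length to the
#' stream) and evaluates every requested metric for every category in
#' every catchment. Per-(catchment, metric) failures (e.g. a degenerate
#' zero denominator under a slope metric in an all-flat catchment) are
#' recorded and do not abort the remaining cells of the table.
#'
#' @param dem a [GridLayer-class] elevation raster.
#' @param landuse a co-registered [LandUseGrid-class].
#' @param streamMask a co-registered [GridLayer-class], nonzero on
#'   stream cells.
#' @param catchments named list of co-registered binary mask
#'   [GridLayer-class] objects; names are catchment ids.
#' @param metrics list of [MetricSpec-class] (default: the canonical 13).
#' @param excludeStream drop stream cells from all sums?
#' @param layers optional precomputed [terrainLayers()] result for this
#'   DEM and stream mask, to avoid recomputation.
#' @return A long-format `data.frame` with columns `catchment_id`,
#'   `metric`, `category`, `percent`, carrying a `data.frame` of recorded
#'   failures (`catchment_id`, `metric`, `error`) in
#'   `attr(, "failures")`.
#' @export
metricSuite <- function(dem, landuse, streamMask, catchments,
                        metrics = canonicalMetrics(),
                        excludeStream = FALSE, layers = NULL) {
  stopifnot(is(dem, "GridLayer"), length(catchments) >= 1)
  stopIfNotCoregistered(dem, landuse, streamMask)
  for (m in catchments) stopIfNotCoregistered(dem, m)
  if (is.null(names(catchments)))
    names(catchments) <- as.character(seq_along(catchments))

  if (is.null(layers)) layers <- terrainLayers(dem, streamMask)
  slope <- layers$slope; accum <- layers$accum
  edist <- layers$edist; flen <- layers$flen

  streamCells <- !is.na(streamMask@values) & streamMask@values != 0
  rows <- list(); fails <- list()
  for (cid in names(catchments)) {
    mask <- catchments[[cid]]
    if (excludeStream) {
      mv <- mask@values
      mv[streamCells] <- 0
      mask <- gridLayer(mv, mask@cellsize, mask@xll, mask@yll)
    }
    for (spec in metrics) {
      res <- tryCatch({
        w <- buildWeightGrid(spec, edist, flen, slope, accum, mask)
        composition(landuse, w)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        fails[[length(fails) + 1L]] <- data.frame(
          catchment_id = cid, metric = spec@name,
          error = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          catchment_id = cid, metric = spec@name, category = names(res),
          percent = unname(res), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "failures") <- if (length(fails))
    do.call(rbind, fails) else
    data.frame(catchment_id = character(), metric = character(),
               error = character(), stringsAsFactors = FALSE)
  out
}

#' Mean and SD of weighted proportions across catchments
#'
#' Summarises a metric table into per-(metric, category) mean and sample
#' standard deviation (n - 1 denominator) across catchments, ordered by
#' the canonical metric order then category.
#'
#' @param table a metric table from [metricSuite()].
#' @return A `data.frame` with columns `metric`, `category`, `mean`,
#'   `sd`, `n`.
#' @export
summarizeProportions <- function(table) {
  stopifnot(all(c("catchment_id", "metric", "category", "percent")
                %in% names(table)))
  if (length(unique(table$catchment_id)) < 2)
    stop("need at least two catchments to summarize")
  agg <- aggregate(percent ~ metric + category, data = table,
                   FUN = function(v) c(mean = mean(v), sd = sd(v),
                                       n = length(v)))
  out <- data.frame(metric = agg$metric, category = agg$category,
                    mean = agg$percent[, "mean"], sd = agg$percent[, "sd"],
                    n = as.integer(agg$percent[, "n"]),
                    stringsAsFactors = FALSE)
  mo <- match(out$metric, metricNames())
  mo[is.na(mo)] <- length(metricNames()) + 1L
  out <- out[order(mo, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
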