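#' @import methods
NULL

#' Virtual raster geometry
#'
#' Common georeferencing for all grid classes: square cells of size
#' \code{cellsize} (map units, metres), lower-left corner at
#' (\code{xll}, \code{yll}), row 1 at the northern edge. Two grids are
#' co-registered iff dimensions, cellsize and origin all match exactly;
#' every multi-grid operation in the package requires co-registration and
#' no resampling is ever performed.
#'
#' @slot cellsize numeric(1), cell edge length in map units (> 0).
#' @slot xll,yll numeric(1), map coordinates of the lower-left corner.
#' @keywords internal
setClass("RasterFrame",
         representation("VIRTUAL",
                        cellsize = "numeric", xll = "numeric",
                        yll = "numeric"))

validRasterFrame <- function(object, nr, nc) {
  msg <- character()
  if (length(object@cellsize) != 1 || !is.finite(object@cellsize) ||
      object@cellsize <= 0)
    msg <- c(msg, "cellsize must be a single positive finite number")
  if (length(object@xll) != 1 || !is.finite(object@xll) ||
      length(object@yll) != 1 || !is.finite(object@yll))
    msg <- c(msg, "xll/yll must be single finite numbers")
  if (nr < 1 || nc < 1)
    msg <- c(msg, "grid must have at least one row and one column")
  msg
}

#' Single-band raster grid
#'
#' The workhorse container for elevation, slope, distance, flow
#' accumulation, weight and mask layers. Values are held as a numeric
#' matrix in row-major, north-up orientation (row 1 = northern edge);
#' nodata is represented in memory as \code{NA} (the on-disk sentinel is
#' handled by \code{\link{readAsciiGrid}} / \code{\link{writeAsciiGrid}}).
#'
#' @slot values numeric matrix; \code{NA} marks nodata, every non-NA entry
#'   is finite.
#' @seealso [gridLayer()] for the user constructor, [gridValues()],
#'   [cellSize()], [sameGeometry()].
#' @export
setClass("GridLayer", contains = "RasterFrame",
         representation(values = "matrix"))

setValidity("GridLayer", function(object) {
  v <- object@values
  msg <- validRasterFrame(object, nrow(v), ncol(v))
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  else if (any(is.infinite(v) | is.nan(v), na.rm = TRUE))
    msg <- c(msg, "non-nodata values must be finite")
  if (length(msg)) msg else TRUE
})

#' D8 flow direction grid
#'
#' Per-cell single-flow-direction (SFD8) codes. Each defined cell drains
#' its entire outflow to exactly one of its 8 neighbours, coded in the
#' fixed scan order 1 = E, 2 = SE, 3 = S, 4 = SW, 5 = W, 6 = NW, 7 = N,
#' 8 = NE (this order also breaks steepest-descent ties). Code 0 marks an
#' outlet: flow leaves the grid or enters nodata. \code{NA} marks an
#' undefined (nodata) cell. Following the codes from any defined cell
#' never revisits a cell.
#'
#' @slot dirs integer matrix of codes in \code{0:8} or \code{NA}.
#' @seealso [d8FlowDirection()], [d8Offsets()].
#' @export
setClass("FlowDirGrid", contains = "RasterFrame",
         representation(dirs = "matrix"))

setValidity("FlowDirGrid", function(object) {
  d <- object@dirs
  msg <- validRasterFrame(object, nrow(d), ncol(d))
  if (!is.integer(d))
    msg <- c(msg, "dirs must be an integer matrix")
  else if (!all(d %in% c(NA_integer_, 0:8)))
    msg <- c(msg, "direction codes must be 0 (outlet), 1..8 or NA")
  if (length(msg)) msg else TRUE
})

#' Categorical land-use grid
#'
#' Integer land-use codes per cell plus a code-to-name map. Houses the
#' indicator I_i(k) (cell i carries category k) used by all composition
#' metrics.
#'
#' @slot codes integer matrix; \code{NA} marks nodata.
#' @slot categories named character vector mapping code (the name, as a
#'   string) to category label, e.g. \code{c(`1` = "forest", `2` = "meadow")}.
#' @seealso [landUseGrid()], [composition()].
#' @export
setClass("LandUseGrid", contains = "RasterFrame",
         representation(codes = "matrix", categories = "character"))

setValidity("LandUseGrid", function(object) {
  k <- object@codes
  msg <- validRasterFrame(object, nrow(k), ncol(k))
  if (!is.integer(k))
    msg <- c(msg, "codes must be an integer matrix")
  if (is.null(names(object@categories)) ||
      anyNA(suppressWarnings(as.integer(names(object@categories)))))
    msg <- c(msg, "categories must be a named character vector with integer names")
  else if (is.integer(k) &&
           !all(k[!is.na(k)] %in% as.integer(names(object@categories))))
    msg <- c(msg, "every non-NA code must appear in the categories map")
  if (length(msg)) msg else TRUE
})

#' Specification of one landscape composition metric
#'
#' A metric is the percentage of a land-use category within a catchment,
#' with each cell weighted by the product of an inverse-distance term
#' (none, Euclidean distance to the stream, or D8 flow-path length to the
#' stream, each as (distance + 1)^-1), optionally the slope gradient in
#' degrees, and optionally flow accumulation (raw or log-transformed).
#' The canonical suite of 13 metrics is returned by
#' \code{\link{canonicalMetrics}}.
#'
#' @slot name character(1), metric label.
#' @slot distance one of \code{"none"}, \code{"euclid"}, \code{"flow"}.
#' @slot useSlope logical(1), multiply weights by slope (degrees)?
#' @slot accumulation one of \code{"none"}, \code{"raw"}, \code{"log"}.
#' @export
setClass("MetricSpec",
         representation(name = "character", distance = "character",
                        useSlope = "logical", accumulation = "character"))

setValidity("MetricSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1 || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (!object@distance %in% c("none", "euclid", "flow"))
    msg <- c(msg, "distance must be 'none', 'euclid' or 'flow'")
  if (!object@accumulation %in% c("none", "raw", "log"))
    msg <- c(msg, "accumulation must be 'none', 'raw' or 'log'")
  if (object@distance == "none" &&
      (isTRUE(object@useSlope) || object@accumulation != "none"))
    msg <- c(msg, "the unweighted metric (distance = 'none') admits no slope or accumulation term")
  if (length(msg)) msg else TRUE
})
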