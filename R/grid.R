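#' Construct raster grid objects
#'
#' `gridLayer()` wraps a numeric matrix as a single-band raster;
#' `flowDirGrid()` wraps an integer matrix of D8 codes; `landUseGrid()`
#' wraps integer category codes plus a code-to-name map. Matrices are
#' north-up: row 1 is the northern edge. `NA` marks nodata.
#'
#' @param values numeric matrix of cell values.
#' @param dirs integer matrix of D8 codes (0 = outlet, 1..8 = E, SE, S,
#'   SW, W, NW, N, NE, `NA` = undefined).
#' @param codes integer matrix of land-use category codes.
#' @param categories named character vector mapping code to label, e.g.
#'   `c("1" = "forest", "2" = "meadow")`.
#' @param cellsize cell edge length in map units (metres).
#' @param xll,yll map coordinates of the lower-left grid corner.
#' @param x a grid object.
#' @return An object of class [GridLayer-class], [FlowDirGrid-class] or
#'   [LandUseGrid-class].
#' @examples
#' g <- gridLayer(matrix(1:9, 3, 3), cellsize = 5)
#' gridDim(g)
#' cellSize(g)
#' @aliases gridValues cellSize gridDim gridOrigin
#' @export
gridLayer <- function(values, cellsize = 1, xll = 0, yll = 0) {
  if (is.vector(values)) values <- matrix(as.numeric(values), nrow = 1)
  storage.mode(values) <- "double"
  new("GridLayer", values = values, cellsize = as.numeric(cellsize),
      xll = as.numeric(xll), yll = as.numeric(yll))
}

#' @rdname gridLayer
#' @aliases flowDirs
#' @export
flowDirGrid <- function(dirs, cellsize = 1, xll = 0, yll = 0) {
  storage.mode(dirs) <- "integer"
  new("FlowDirGrid", dirs = dirs, cellsize = as.numeric(cellsize),
      xll = as.numeric(xll), yll = as.numeric(yll))
}

#' @rdname gridLayer
#' @aliases landUseCodes categories
#' @export
landUseGrid <- function(codes, categories, cellsize = 1, xll = 0, yll = 0) {
  storage.mode(codes) <- "integer"
  new("LandUseGrid", codes = codes, categories = categories,
      cellsize = as.numeric(cellsize), xll = as.numeric(xll),
      yll = as.numeric(yll))
}

#' @rdname gridLayer
setMethod("gridValues", "GridLayer", function(x) x@values)

#' @rdname gridLayer
setMethod("cellSize", "RasterFrame", function(x) x@cellsize)

#' @rdname gridLayer
setMethod("gridOrigin", "RasterFrame", function(x) c(xll = x@xll, yll = x@yll))

#' @rdname gridLayer
setMethod("gridDim", "GridLayer", function(x) dim(x@values))

#' @rdname gridLayer
setMethod("gridDim", "FlowDirGrid", function(x) dim(x@dirs))

#' @rdname gridLayer
setMethod("gridDim", "LandUseGrid", function(x) dim(x@codes))

#' @rdname gridLayer
setMethod("flowDirs", "FlowDirGrid", function(x) x@dirs)

#' @rdname gridLayer
setMethod("landUseCodes", "LandUseGrid", function(x) x@codes)

#' @rdname gridLayer
setMethod("categories", "LandUseGrid", function(x) x@categories)

#' Test exact co-registration of two grids
#'
#' Two grids are co-registered iff their dimensions, cell size and
#' lower-left origin match exactly. All multi-grid operations require
#' this; no resampling is ever performed.
#'
#' @param x,y grid objects (any mix of [GridLayer-class],
#'   [FlowDirGrid-class], [LandUseGrid-class]).
#' @return `TRUE` or `FALSE`.
#' @export
setMethod("sameGeometry", signature("RasterFrame", "RasterFrame"),
          function(x, y) {
  identical(gridDim(x), gridDim(y)) &&
    isTRUE(x@cellsize == y@cellsize) &&
    isTRUE(x@xll == y@xll) && isTRUE(x@yll == y@yll)
})

stopIfNotCoregistered <- function(...) {
  grids <- list(...)
  grids <- grids[!vapply(grids, is.null, logical(1))]
  if (length(grids) < 2) return(invisible(TRUE))
  for (i in seq_along(grids)[-1])
    if (!sameGeometry(grids[[1]], grids[[i]]))
      stop("grids are not co-registered", call. = FALSE)
  invisible(TRUE)
}

showFrame <- function(object, what, extra = "") {
  d <- gridDim(object)
  cat(sprintf("%s: %d x %d cells, cellsize %g, origin (%g, %g)%s\n",
              what, d[1], d[2], object@cellsize, object@xll, object@yll,
              extra))
}

setMethod("show", "GridLayer", function(object) {
  v <- object@values
  rng <- if (all(is.na(v))) "all nodata" else
    sprintf("range [%g, %g], %d nodata", min(v, na.rm = TRUE),
            max(v, na.rm = TRUE), sum(is.na(v)))
  showFrame(object, "GridLayer", paste0("; ", rng))
})

setMethod("show", "FlowDirGrid", function(object) {
  d <- object@dirs
  showFrame(object, "FlowDirGrid",
            sprintf("; %d outlets, %d undefined", sum(d == 0, na.rm = TRUE),
                    sum(is.na(d))))
})

setMethod("show", "LandUseGrid", function(object) {
  showFrame(object, "LandUseGrid",
            paste0("; categories: ",
                   paste(sprintf("%s=%s", names(object@categories),
                                 object@categories), collapse = ", ")))
})

setMethod("show", "MetricSpec", function(object) {
  cat(sprintf("MetricSpec '%s': distance=%s, slope=%s, accumulation=%s\n",
              object@name, object@distance, object@useSlope,
              object@accumulation))
})

#' D8 neighbour offsets and step lengths
#'
#' The fixed neighbour scan order used throughout the package, both for
#' direction codes and for breaking steepest-descent ties: E, SE, S, SW,
#' W, NW, N, NE. Row offsets are in matrix orientation (row 1 = north, so
#' +1 row = one cell south).
#'
#' @return A data.frame with columns `code`, `dr`, `dc` and `distMult`
#'   (step length in cells: 1 cardinal, sqrt(2) diagonal).
#' @export
d8Offsets <- function() {
  data.frame(code = 1:8,
             dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
             dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
             distMult = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))
}
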