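#' Fill depressions in a DEM (priority-flood)
#'
#' Raises every cell to the minimal spill elevation over all 8-connected
#' paths to the grid edge (or to a nodata cell, which also acts as an
#' exit), so that every defined cell has a monotonically non-increasing
#' path off the grid. Cells not inside a depression are unchanged; no
#' epsilon gradient is imposed, so filled depressions become exact flats.
#' The operation is idempotent.
#'
#' @param dem a [GridLayer-class] of elevations (metres).
#' @return A co-registered [GridLayer-class] with `output >= input`
#'   everywhere.
#' @examples
#' dem <- gridLayer(matrix(c(5,5,5, 5,1,5, 5,5,5), 3, 3, byrow = TRUE))
#' gridValues(fillDepressions(dem))[2, 2]  # pit raised to rim minimum: 5
#' @export
fillDepressions <- function(dem) {
  stopifnot(is(dem, "GridLayer"))
  if (all(is.na(dem@values))) stop("empty DEM")
  gridLayer(cpp_fill_depressions(dem@values), dem@cellsize, dem@xll, dem@yll)
}

#' Slope gradient in degrees (Horn's method)
#'
#' Third-order finite difference on the 3x3 neighbourhood (Horn 1981),
#' the estimator used by ArcGIS Slope. Edge cells use replicated-edge
#' padding; a nodata neighbour is substituted by the centre value, and a
#' nodata centre propagates. A single-cell grid has slope 0 (degenerate
#' neighbourhood). Slope is computed on the raw DEM, not the filled one.
#'
#' @param dem a [GridLayer-class] of elevations (metres).
#' @return A co-registered [GridLayer-class] of slope in degrees,
#'   in `[0, 90)`.
#' @export
slopeGrid <- function(dem) {
  stopifnot(is(dem, "GridLayer"))
  z <- dem@values
  nr <- nrow(z); nc <- ncol(z)
  # replicate-pad, then substitute nodata neighbours by the centre value
  pad <- z[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc), drop = FALSE]
  shift <- function(dr, dc) {
    w <- pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc), drop = FALSE]
    bad <- is.na(w) & !is.na(z)
    w[bad] <- z[bad]
    w
  }
  a <- shift(0, 0); b <- shift(0, 1); cc <- shift(0, 2)
  d <- shift(1, 0);                   f <- shift(1, 2)
  g <- shift(2, 0); h <- shift(2, 1); i <- shift(2, 2)
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * dem@cellsize)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * dem@cellsize)
  s <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  s[is.na(z)] <- NA_real_
  gridLayer(s, dem@cellsize, dem@xll, dem@yll)
}

#' D8 (SFD8) flow direction
#'
#' Assigns each cell's entire outflow to the neighbour with the maximal
#' positive drop per unit distance (distance = cellsize for cardinal,
#' cellsize * sqrt(2) for diagonal neighbours); ties break by the fixed
#' scan order E, SE, S, SW, W, NW, N, NE (see [d8Offsets()]). Flat cells
#' adjacent to nodata drain into it (code 0, outlet); the remaining flats
#' are resolved by a breadth-first pass that points each flat cell toward
#' the nearest already-resolved cell of equal elevation, and flat regions
#' with no internal drainage exit the grid at their border cells. On a
#' depression-filled DEM the result is acyclic and complete.
#'
#' @param filledDem a depression-filled [GridLayer-class]
#'   (see [fillDepressions()]).
#' @return A [FlowDirGrid-class].
#' @export
d8FlowDirection <- function(filledDem) {
  stopifnot(is(filledDem, "GridLayer"))
  flowDirGrid(cpp_d8_flow_direction(filledDem@values),
              filledDem@cellsize, filledDem@xll, filledDem@yll)
}

#' D8 flow accumulation (self-inclusive)
#'
#' Counts, for every cell, the number of cells whose D8 flow path passes
#' through or starts at it, including the cell itself, so the minimum is
#' 1 at ridge cells. The self-inclusive convention keeps ln(A) finite for
#' the log-accumulation metrics: ridge cells get ln(1) = 0 and simply
#' contribute nothing there. Computed in topological order.
#'
#' @param dirs a [FlowDirGrid-class] (must be acyclic).
#' @return A co-registered [GridLayer-class] of counts (>= 1).
#' @export
flowAccumulation <- function(dirs) {
  stopifnot(is(dirs, "FlowDirGrid"))
  gridLayer(cpp_flow_accumulation(dirs@dirs), dirs@cellsize, dirs@xll,
            dirs@yll)
}

#' Euclidean distance to the stream network
#'
#' Exact straight-line distance (metres) from each cell centre to the
#' nearest stream-cell centre; stream cells get 0. This is the raw
#' distance d; the metrics apply the (d + 1)^-1 decay themselves.
#'
#' @param streamMask a [GridLayer-class] with nonzero values on stream
#'   cells.
#' @return A co-registered [GridLayer-class] of distances in map units.
#' @export
euclideanDistanceToStream <- function(streamMask) {
  stopifnot(is(streamMask, "GridLayer"))
  m <- !is.na(streamMask@values) & streamMask@values != 0
  if (!any(m)) stop("empty stream network")
  gridLayer(cpp_euclid_dist(m, streamMask@cellsize), streamMask@cellsize,
            streamMask@xll, streamMask@yll)
}

#' D8 flow-path length to the stream
#'
#' Downslope along-path distance (metres) from each cell centre to the
#' first stream cell on its D8 path, summing cellsize per cardinal step
#' and cellsize * sqrt(2) per diagonal step. Stream cells get 0. Cells
#' whose path exits the grid (outlet) without meeting a stream cell get
#' nodata; such cells are excluded from both numerator and denominator of
#' the flow-distance metrics, and in catchments delineated from the same
#' DEM the excluded set is empty by construction.
#'
#' @param dirs a [FlowDirGrid-class] (acyclic).
#' @param streamMask a co-registered [GridLayer-class], nonzero on stream
#'   cells.
#' @return A co-registered [GridLayer-class] of distances in map units.
#' @export
flowLengthToStream <- function(dirs, streamMask) {
  stopifnot(is(dirs, "FlowDirGrid"), is(streamMask, "GridLayer"))
  stopIfNotCoregistered(dirs, streamMask)
  m <- !is.na(streamMask@values) & streamMask@values != 0
  gridLayer(cpp_flow_length(dirs@dirs, m, dirs@cellsize), dirs@cellsize,
            dirs@xll, dirs@yll)
}

#' Delineate the catchment draining through an outlet cell
#'
#' Returns the binary mask of all cells whose D8 flow path passes through
#' the outlet cell (the outlet itself included).
#'
#' @param dirs a [FlowDirGrid-class].
#' @param outlet integer `c(row, col)`, 1-based matrix indices of the
#'   outlet cell (row 1 = northern edge).
#' @return A co-registered [GridLayer-class] mask (1 inside, 0 outside,
#'   `NA` on undefined cells).
#' @export
delineateCatchment <- function(dirs, outlet) {
  stopifnot(is(dirs, "FlowDirGrid"), length(outlet) == 2)
  m <- cpp_delineate(dirs@dirs, as.integer(outlet[1]) - 1L,
                     as.integer(outlet[2]) - 1L)
  storage.mode(m) <- "double"
  gridLayer(m, dirs@cellsize, dirs@xll, dirs@yll)
}
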