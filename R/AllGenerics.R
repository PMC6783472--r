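#' @rdname gridLayer
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname gridLayer
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname gridLayer
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname gridLayer
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname sameGeometry
#' @export
setGeneric("sameGeometry", function(x, y) standardGeneric("sameGeometry"))

#' @rdname flowDirGrid
#' @export
setGeneric("flowDirs", function(x) standardGeneric("flowDirs"))

#' @rdname landUseGrid
#' @export
setGeneric("landUseCodes", function(x) standardGeneric("landUseCodes"))

#' @rdname landUseGrid
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
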