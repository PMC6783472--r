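# Shared toy fixtures: an east-tilted 3x3 plane with the stream along
# the eastern column, cellsize 5 m, forest in the western column.
eastPlane <- function(cellsize = 5) {
  dem <- gridLayer(matrix(c(2, 1, 0, 2, 1, 0, 2, 1, 0), 3, 3,
                          byrow = TRUE), cellsize)
  stream <- gridLayer(matrix(c(0, 0, 1, 0, 0, 1, 0, 0, 1), 3, 3,
                             byrow = TRUE), cellsize)
  landuse <- landUseGrid(matrix(c(1, 2, 2, 1, 2, 2, 1, 2, 2), 3, 3,
                                byrow = TRUE),
                         c("1" = "forest", "2" = "meadow"), cellsize)
  mask <- gridLayer(matrix(1, 3, 3), cellsize)
  list(dem = dem, stream = stream, landuse = landuse, mask = mask)
}

# small synthetic catchment for metric property tests
smallConfig <- function(...) synthConfig(nCatchments = 1, nrow = 40,
                                         ncol = 40, streamThreshold = 40,
                                         minCatchmentFraction = 0.2, ...)
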