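#' Read an ESRI ASCII grid
#'
#' Parses the standard `.asc` dialect: a header with keys `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize` and (optionally)
#' `NODATA_value` — keys are case-insensitive — followed by
#' whitespace-separated values, row 1 = northern edge. Nodata cells
#' become `NA`. Malformed input (missing header key, non-numeric token,
#' ragged or missing rows) raises an error naming the offending line.
#'
#' @param path file path.
#' @return A [GridLayer-class].
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) == 2 && grepl("^[A-Za-z_]", tok[1])) {
      val <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(val))
        stop(sprintf("line %d: non-numeric header value '%s'", i, tok[2]))
      hdr[[tolower(tok[1])]] <- val
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("missing header key(s): ", paste(missing, collapse = ", "))
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999

  dataLines <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  if (length(dataLines) != nr)
    stop(sprintf("line %d: expected %d data rows, found %d", i, nr,
                 length(dataLines)))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    tok <- strsplit(trimws(dataLines[r]), "\\s+")[[1]]
    if (length(tok) != nc)
      stop(sprintf("line %d: expected %d values, found %d", i + r - 1L,
                   nc, length(tok)))
    v <- suppressWarnings(as.numeric(tok))
    if (anyNA(v))
      stop(sprintf("line %d: non-numeric token '%s'", i + r - 1L,
                   tok[which(is.na(v))[1]]))
    vals[r, ] <- v
  }
  vals[vals == nodata] <- NA_real_
  gridLayer(vals, hdr$cellsize, hdr$xllcorner, hdr$yllcorner)
}

#' Write an ESRI ASCII grid
#'
#' Real-valued grids are written with 6 significant digits; grids whose
#' defined values are all whole numbers (masks, categorical codes) are
#' written as integers. Nodata is written as the sentinel (-9999 by
#' default). Round-trips through [readAsciiGrid()] are lossless within
#' the writer precision.
#'
#' @param grid a [GridLayer-class] (or [LandUseGrid-class], written as
#'   integer codes).
#' @param path output file path.
#' @param nodata sentinel value for `NA` cells.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  if (is(grid, "LandUseGrid")) {
    v <- grid@codes
    storage.mode(v) <- "double"
  } else {
    stopifnot(is(grid, "GridLayer"))
    v <- grid@values
  }
  intLike <- all(is.na(v) | v == round(v))
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", grid@xll),
           sprintf("yllcorner %.10g", grid@yll),
           sprintf("cellsize %.10g", grid@cellsize),
           sprintf("NODATA_value %.10g", nodata))
  fmt <- function(row) {
    s <- if (intLike) sprintf("%d", as.integer(row))
         else sprintf("%.6g", signif(row, 6))
    s[is.na(row)] <- if (intLike) sprintf("%d", as.integer(nodata))
                     else sprintf("%.6g", nodata)
    paste(s, collapse = " ")
  }
  body <- apply(v, 1, fmt)
  writeLines(c(hdr, body), path)
  invisible(path)
}
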