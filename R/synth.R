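#' Configuration for the synthetic catchment generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 37 small headwater catchments on a 5 m DEM in hilly terrain, dominated
#' by two spatially autocorrelated land-use categories (forest and
#' meadow) whose areal share spans roughly 15-96 percent, and
#' water-quality values generated as a linear function of one chosen
#' metric plus Gaussian homoscedastic noise.
#'
#' @param nCatchments number of catchments (default 37).
#' @param nrow,ncol grid size per catchment in cells (default 120 x 120).
#' @param cellsize cell size in metres (default 5).
#' @param reliefAmplitude relief of the random surface in metres
#'   (approximately 4 standard deviations of the noise field; 0 gives a
#'   pure tilted valley plane).
#' @param spectralDecay spectral decay exponent of the terrain noise
#'   (larger = smoother hills).
#' @param luCorrelationLength land-use autocorrelation length in cells
#'   (0 gives a salt-and-pepper mosaic).
#' @param forestRange range the per-catchment forest target fraction is
#'   drawn from, uniformly.
#' @param streamThreshold flow-accumulation threshold (cells) defining
#'   the stream network.
#' @param tiltDown,tiltCross down-valley and cross-valley gradients
#'   (m/m) of the deterministic valley added to the noise so the filled
#'   DEM drains to a single dominant outlet.
#' @param baseElevation cosmetic elevation offset in metres.
#' @param minCatchmentFraction minimum fraction of grid cells the
#'   delineated catchment must cover; smaller draws are regenerated with
#'   an incremented sub-seed.
#' @param wqpGenerators named list of response generators; each element
#'   is `list(metric, category, beta0, beta1, noiseSd)` or with
#'   `targetR2` instead of `noiseSd` (the noise SD is then derived so the
#'   population R^2 of the generating regression equals `targetR2`).
#' @return A classed list (`synthConfig`).
#' @export
synthConfig <- function(nCatchments = 37, nrow = 120, ncol = 120,
                        cellsize = 5, reliefAmplitude = 15,
                        spectralDecay = 2.2, luCorrelationLength = 12,
                        forestRange = c(0.15, 0.96),
                        streamThreshold = 150, tiltDown = 0.03,
                        tiltCross = 0.05, baseElevation = 600,
                        minCatchmentFraction = 0.3,
                        wqpGenerators = list(
                          wqp_proximal = list(metric = "Euclid-S",
                                              category = "forest",
                                              beta0 = 5, beta1 = 0.1,
                                              targetR2 = 0.6),
                          wqp_composition = list(metric = "Unweighted",
                                                 category = "forest",
                                                 beta0 = 10, beta1 = 0.2,
                                                 targetR2 = 0.6))) {
  stopifnot(nCatchments >= 1, nrow >= 3, ncol >= 3, cellsize > 0,
            reliefAmplitude >= 0, luCorrelationLength >= 0,
            length(forestRange) == 2, forestRange[1] > 0,
            forestRange[2] < 1, forestRange[1] <= forestRange[2],
            streamThreshold >= 1)
  structure(list(nCatchments = nCatchments, nrow = nrow, ncol = ncol,
                 cellsize = cellsize, reliefAmplitude = reliefAmplitude,
                 spectralDecay = spectralDecay,
                 luCorrelationLength = luCorrelationLength,
                 forestRange = forestRange,
                 streamThreshold = streamThreshold, tiltDown = tiltDown,
                 tiltCross = tiltCross, baseElevation = baseElevation,
                 minCatchmentFraction = minCatchmentFraction,
                 wqpGenerators = wqpGenerators),
            class = "synthConfig")
}

# Spectrally filtered Gaussian random field, standardized to mean 0 sd 1.
# `amp` maps radial frequency (cycles per cell) to filter amplitude.
spectralField <- function(nr, nc, amp) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  fr <- seq_len(nr) - 1L; fr[fr > nr / 2] <- fr[fr > nr / 2] - nr
  fc <- seq_len(nc) - 1L; fc[fc > nc / 2] <- fc[fc > nc / 2] - nc
  kr <- sqrt(outer((fr / nr)^2, (fc / nc)^2, "+"))
  a <- amp(kr)
  a[1, 1] <- 0  # remove the DC component
  f <- Re(stats::fft(stats::fft(noise) * a, inverse = TRUE)) / (nr * nc)
  s <- stats::sd(f)
  if (s == 0) return(f)
  (f - mean(f)) / s
}

#' Generate a synthetic drainable DEM
#'
#' Spectrally filtered Gaussian noise (power-law decay, giving smooth
#' hilly terrain) superimposed on a deterministic valley: a down-valley
#' tilt toward the eastern edge plus a cross-valley slope toward the
#' central row, so that after depression filling the grid drains to a
#' dominant outlet on the east edge. Fully deterministic given the seed.
#'
#' @param config a [synthConfig()].
#' @param seed optional integer; if given, the RNG is seeded locally.
#' @return A [GridLayer-class] with no nodata.
#' @export
genDEM <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nr <- config$nrow; nc <- config$ncol; cs <- config$cellsize
  decay <- config$spectralDecay
  k0 <- 1 / max(nr, nc)
  noise <- if (config$reliefAmplitude > 0)
    spectralField(nr, nc, function(k) (k + k0)^(-decay)) *
      (config$reliefAmplitude / 4) else matrix(0, nr, nc)
  col <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  row <- matrix(rep(seq_len(nr), nc), nr, nc)
  valley <- config$tiltDown * cs * (nc - col) +
    config$tiltCross * cs * abs(row - (nr + 1) / 2)
  gridLayer(config$baseElevation + valley + noise, cs)
}

#' Generate a two-category autocorrelated land-use mosaic
#'
#' Thresholds a spectrally smoothed Gaussian random field so that the
#' forest share of the reference cells (the catchment mask if given,
#' otherwise the whole grid) hits the target fraction; the rest is
#' meadow. The Gaussian spectral filter gives spatially contiguous
#' patches at the configured correlation length; length 0 degenerates to
#' an uncorrelated salt-and-pepper mosaic.
#'
#' @param config a [synthConfig()].
#' @param seed optional integer seed.
#' @param forestFraction target forest fraction; drawn uniformly from
#'   `config$forestRange` when `NULL`.
#' @param mask optional [GridLayer-class]; the threshold quantile is
#'   taken over nonzero mask cells.
#' @return A [LandUseGrid-class] with categories
#'   `c("1" = "forest", "2" = "meadow")`.
#' @export
genLanduse <- function(config, seed = NULL, forestFraction = NULL,
                       mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(forestFraction))
    forestFraction <- stats::runif(1, config$forestRange[1],
                                   config$forestRange[2])
  nr <- config$nrow; nc <- config$ncol
  L <- config$luCorrelationLength
  field <- if (L > 0)
    spectralField(nr, nc, function(k) exp(-(k * L)^2 / 2))
  else matrix(stats::rnorm(nr * nc), nr, nc)
  ref <- if (is.null(mask)) field else
    field[!is.na(mask@values) & mask@values != 0]
  thr <- stats::quantile(ref, 1 - forestFraction, names = FALSE, type = 7)
  codes <- ifelse(field >= thr, 1L, 2L)
  landUseGrid(matrix(codes, nr, nc), c("1" = "forest", "2" = "meadow"),
              config$cellsize)
}

#' Derive the stream network from flow accumulation
#'
#' Stream cells are those with self-inclusive flow accumulation at or
#' above the threshold. If no cell qualifies the threshold is lowered to
#' the grid maximum (a single-cell stream) with a warning, so the result
#' is never empty.
#'
#' @param dirs a [FlowDirGrid-class] (unused beyond geometry, kept for
#'   interface symmetry).
#' @param accum accumulation [GridLayer-class] from [flowAccumulation()].
#' @param threshold accumulation threshold in cells.
#' @return A binary stream-mask [GridLayer-class].
#' @export
genStreams <- function(dirs, accum, threshold) {
  stopifnot(is(accum, "GridLayer"))
  a <- accum@values
  mx <- max(a, na.rm = TRUE)
  if (mx < threshold) {
    warning(sprintf("stream threshold %g exceeds max accumulation %g; lowered",
                    threshold, mx))
    threshold <- mx
  }
  m <- ifelse(!is.na(a) & a >= threshold, 1, 0)
  m[is.na(a)] <- NA_real_
  gridLayer(m, accum@cellsize, accum@xll, accum@yll)
}

#' Noise SD giving a target population R-squared
#'
#' For a response `beta0 + beta1 * x + N(0, sd^2)`, the population
#' R-squared is `beta1^2 var(x) / (beta1^2 var(x) + sd^2)`; this solves
#' for `sd` given the realized predictor values.
#'
#' @param beta1 generating slope.
#' @param x realized predictor values.
#' @param targetR2 desired population R-squared in (0, 1].
#' @return The noise standard deviation.
#' @export
noiseSdForR2 <- function(beta1, x, targetR2) {
  stopifnot(targetR2 > 0, targetR2 <= 1)
  s <- if (length(x) < 2) 0 else stats::sd(x)  # no spread, no noise
  abs(beta1) * s * sqrt((1 - targetR2) / targetR2)
}

#' Generate synthetic water-quality tables from a metric table
#'
#' Each configured parameter is a linear function of one generating
#' metric and category (`value = beta0 + beta1 * %LU + N(0, sd)`), with
#' the noise SD either given or derived from a target population
#' R-squared. The generating structure matches the assumption of the
#' downstream single-predictor regressions.
#'
#' @param metricTable a metric table from [metricSuite()].
#' @param generators named list of generator specs (see [synthConfig()]).
#' @param seed optional integer seed.
#' @return A `data.frame` with columns `catchment_id`, `parameter`,
#'   `value`.
#' @export
genWQP <- function(metricTable, generators, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (p in names(generators)) {
    g <- generators[[p]]
    sub <- metricTable[metricTable$metric == g$metric &
                         metricTable$category == g$category, , drop = FALSE]
    if (!nrow(sub))
      stop(sprintf("generating metric '%s' / category '%s' not in table",
                   g$metric, g$category))
    sub <- sub[order(sub$catchment_id), , drop = FALSE]
    sd <- if (!is.null(g$noiseSd)) g$noiseSd
          else noiseSdForR2(g$beta1, sub$percent, g$targetR2)
    out[[p]] <- data.frame(
      catchment_id = sub$catchment_id, parameter = p,
      value = g$beta0 + g$beta1 * sub$percent +
        stats::rnorm(nrow(sub), 0, sd),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic study set
#'
#' Produces, per catchment, a drainable DEM, terrain layers, a stream
#' network, the catchment mask (delineated at the maximal-accumulation
#' cell) and a two-category land-use mosaic, then the metric table and a
#' water-quality table with a known generating metric. A catchment draw
#' whose mask is too small or whose 13 metric denominators are not all
#' positive is regenerated with an incremented sub-seed; the count is
#' recorded. Everything is deterministic given `seed`.
#'
#' @param config a [synthConfig()].
#' @param seed integer master seed; all per-catchment sub-seeds and the
#'   response noise derive from it.
#' @return A classed list (`studySet`) with elements `catchments` (each
#'   holding `dem`, `landuse`, `streams`, `mask`, `outlet`,
#'   `forestTarget`), `metrics`, `wqp`, `config`, `seed`,
#'   `regenerations`.
#' @export
generateStudySet <- function(config, seed) {
  stopifnot(inherits(config, "synthConfig"))
  set.seed(seed)
  n <- config$nCatchments
  maxAttempts <- 25L
  subSeeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                n * maxAttempts), maxAttempts, n)
  fractions <- stats::runif(n, config$forestRange[1], config$forestRange[2])
  wqpSeed <- sample.int(.Machine$integer.max - 1L, 1)

  catchments <- vector("list", n)
  names(catchments) <- sprintf("c%02d", seq_len(n))
  regen <- 0L
  for (i in seq_len(n)) {
    done <- FALSE
    for (attempt in seq_len(maxAttempts)) {
      s <- subSeeds[attempt, i]
      dem <- genDEM(config, seed = s)
      filled <- fillDepressions(dem)
      dirs <- d8FlowDirection(filled)
      accum <- flowAccumulation(dirs)
      streams <- suppressWarnings(
        genStreams(dirs, accum, config$streamThreshold))
      outlet <- which(accum@values == max(accum@values), arr.ind = TRUE)[1, ]
      mask <- delineateCatchment(dirs, outlet)
      nIn <- sum(mask@values != 0, na.rm = TRUE)
      if (nIn < config$minCatchmentFraction * config$nrow * config$ncol) {
        regen <- regen + 1L
        next
      }
      slope <- slopeGrid(dem)
      edist <- euclideanDistanceToStream(streams)
      flen <- flowLengthToStream(dirs, streams)
      okDenoms <- all(vapply(canonicalMetrics(), function(spec) {
        w <- tryCatch(buildWeightGrid(spec, edist, flen, slope, accum,
                                      mask)@values,
                      error = function(e) NA_real_)
        isTRUE(sum(w, na.rm = TRUE) > 0) && !all(is.na(w))
      }, logical(1)))
      if (!okDenoms || all(is.na(flen@values[mask@values != 0]))) {
        regen <- regen + 1L
        next
      }
      landuse <- genLanduse(config, seed = (s %% (.Machine$integer.max - 2L)) + 1L,
                            forestFraction = fractions[i], mask = mask)
      catchments[[i]] <- list(dem = dem, landuse = landuse,
                              streams = streams, mask = mask,
                              outlet = outlet,
                              forestTarget = fractions[i], subSeed = s,
                              layers = list(filled = filled, slope = slope,
                                            dirs = dirs, accum = accum,
                                            edist = edist, flen = flen))
      done <- TRUE
      break
    }
    if (!done)
      stop(sprintf("catchment %d: no viable draw in %d attempts", i,
                   maxAttempts))
  }

  metrics <- studySetMetrics(
    structure(list(catchments = catchments), class = "studySet"))
  wqp <- genWQP(metrics, config$wqpGenerators, seed = wqpSeed)
  structure(list(catchments = catchments, metrics = metrics, wqp = wqp,
                 config = config, seed = seed, regenerations = regen),
            class = "studySet")
}

#' Metric table of a study set
#'
#' Runs [metricSuite()] independently on every catchment grid of a study
#' set and binds the results into one long table.
#'
#' @param set a `studySet` (or any list with a `catchments` element of
#'   the same shape).
#' @param metrics list of [MetricSpec-class] (default: canonical 13).
#' @param excludeStream drop stream cells from the sums?
#' @return A long metric `data.frame` (see [metricSuite()]), failures
#'   bound in `attr(, "failures")`.
#' @export
studySetMetrics <- function(set, metrics = canonicalMetrics(),
                            excludeStream = FALSE) {
  tabs <- lapply(names(set$catchments), function(cid) {
    cm <- set$catchments[[cid]]
    masks <- list(cm$mask)
    names(masks) <- cid
    metricSuite(cm$dem, cm$landuse, cm$streams, masks, metrics,
                excludeStream, layers = cm$layers)
  })
  out <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
  attr(out, "failures") <- do.call(rbind, lapply(tabs, attr, "failures"))
  out
}

#' Write a study set to disk
#'
#' One subdirectory per catchment with `dem.asc`, `landuse.asc`,
#' `streams.asc` and `mask.asc` (ESRI ASCII), plus `wqp.csv` and a JSON
#' manifest recording the configuration, master seed, per-catchment
#' sub-seeds and the regeneration count.
#'
#' @param set a `studySet` from [generateStudySet()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudySet <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cid in names(set$catchments)) {
    cm <- set$catchments[[cid]]
    sub <- file.path(dir, cid)
    dir.create(sub, showWarnings = FALSE)
    writeAsciiGrid(cm$dem, file.path(sub, "dem.asc"))
    writeAsciiGrid(cm$landuse, file.path(sub, "landuse.asc"))
    writeAsciiGrid(cm$streams, file.path(sub, "streams.asc"))
    writeAsciiGrid(cm$mask, file.path(sub, "mask.asc"))
  }
  utils::write.csv(set$wqp, file.path(dir, "wqp.csv"), row.names = FALSE)
  manifest <- list(config = unclass(set$config), seed = set$seed,
                   regenerations = set$regenerations,
                   catchments = lapply(set$catchments, function(cm)
                     list(subSeed = cm$subSeed,
                          forestTarget = cm$forestTarget,
                          outlet = as.integer(cm$outlet))),
                   categories = list("1" = "forest", "2" = "meadow"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
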