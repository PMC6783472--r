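#' Read a study set written by [writeStudySet()]
#'
#' @param dir directory containing per-catchment subdirectories,
#'   `wqp.csv` and `manifest.json`.
#' @return A `studySet`-shaped list with `catchments`, `wqp` and
#'   `manifest`.
#' @export
readStudySet <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cids <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE))
  cats <- manifest$categories
  if (is.null(cats)) cats <- c("1" = "forest", "2" = "meadow")
  cats <- stats::setNames(as.character(cats), names(cats))
  catchments <- lapply(cids, function(cid) {
    sub <- file.path(dir, cid)
    lu <- readAsciiGrid(file.path(sub, "landuse.asc"))
    codes <- lu@values
    storage.mode(codes) <- "integer"
    list(dem = readAsciiGrid(file.path(sub, "dem.asc")),
         landuse = landUseGrid(codes, cats, lu@cellsize, lu@xll, lu@yll),
         streams = readAsciiGrid(file.path(sub, "streams.asc")),
         mask = readAsciiGrid(file.path(sub, "mask.asc")))
  })
  names(catchments) <- cids
  wqp <- utils::read.csv(file.path(dir, "wqp.csv"),
                         stringsAsFactors = FALSE)
  structure(list(catchments = catchments, wqp = wqp, manifest = manifest),
            class = "studySet")
}

pipelineLog <- function(lines, msg) c(lines, msg)

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end comparison: obtain the study inputs
#' (either generated synthetically from a configuration + seed, or read
#' from a study-set directory), compute the landscape composition metric
#' table, summarize proportions, correlate metrics pairwise, fit one
#' regression per (parameter, metric, category) and rank metrics by R^2.
#' All tables are written as CSV into `outDir` together with a
#' machine-readable log (`WARN`/`INFO` lines with per-stage timings).
#' Output CSVs are deterministic: rerunning on the same inputs
#' reproduces them byte for byte.
#'
#' @param config either a path to a JSON file or a list, with elements:
#'   `synth` (arguments for [synthConfig()]) plus `seed`, or `input_dir`
#'   (a directory from [writeStudySet()]); optional `metrics` (names
#'   from [metricNames()] to run), `categories` (category names kept in
#'   the statistical stage), `alpha`, `exclude`
#'   (`data.frame`/records with `catchment_id`, `parameter`),
#'   `drop_parameters`, `exclude_stream`, `adjust` (`"none"`/`"BH"`).
#' @param outDir output directory, created if needed.
#' @return Invisibly, a list with the computed `metrics`, `summary`,
#'   `correlations`, `results`, `ranking`, the `set` used, and the paths
#'   written.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  t0 <- proc.time()[["elapsed"]]
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    line <- sprintf("INFO stage=%s seconds=%.2f", stage, t1 - t0)
    t0 <<- t1
    line
  }

  warnings_seen <- character()
  withCallingHandlers({
    # -- inputs -----------------------------------------------------------
    if (!is.null(config$synth)) {
      scfg <- do.call(synthConfig, config$synth)
      if (is.null(config$seed)) stop("synth pipeline requires a seed")
      set <- generateStudySet(scfg, seed = config$seed)
      if (set$regenerations > 0)
        warnings_seen <- c(warnings_seen,
          sprintf("WARN stage=synth regenerated_draws=%d",
                  set$regenerations))
    } else if (!is.null(config$input_dir)) {
      set <- readStudySet(config$input_dir)
    } else stop("config must provide either 'synth' (+ seed) or 'input_dir'")
    log <- pipelineLog(log, tick("inputs"))

    # -- metric table -----------------------------------------------------
    specs <- canonicalMetrics()
    if (!is.null(config$metrics)) {
      unknown <- setdiff(config$metrics, names(specs))
      if (length(unknown))
        stop("unknown metric name(s): ", paste(unknown, collapse = ", "))
      specs <- specs[config$metrics]
    }
    metrics <- studySetMetrics(set, metrics = specs,
                               excludeStream = isTRUE(config$exclude_stream))
    fails <- attr(metrics, "failures")
    if (nrow(fails))
      warnings_seen <- c(warnings_seen, sprintf(
        "WARN stage=metrics catchment=%s metric=%s error=%s",
        fails$catchment_id, fails$metric, fails$error))
    if (!is.null(config$categories))
      metricsStat <- metrics[metrics$category %in% config$categories, ,
                             drop = FALSE]
    else metricsStat <- metrics
    log <- pipelineLog(log, tick("metrics"))

    # -- summaries, correlations, regressions -----------------------------
    summ <- summarizeProportions(metricsStat)
    cors <- lapply(unique(metricsStat$category), function(cat)
      pearsonMatrix(metricsStat, cat))
    names(cors) <- unique(metricsStat$category)
    alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
    exclude <- if (!is.null(config$exclude))
      as.data.frame(config$exclude) else NULL
    cmp <- compareMetrics(metricsStat, set$wqp, alpha = alpha,
                          exclude = exclude,
                          dropParameters = config$drop_parameters,
                          adjust = if (is.null(config$adjust)) "none"
                                   else config$adjust)
    log <- pipelineLog(log, tick("stats"))
  }, warning = function(w) {
    warnings_seen <<- c(warnings_seen,
                        paste("WARN", conditionMessage(w)))
    invokeRestart("muffleWarning")
  })

  # -- outputs ------------------------------------------------------------
  paths <- list(
    metrics = file.path(outDir, "metrics.csv"),
    failures = file.path(outDir, "failures.csv"),
    summary = file.path(outDir, "summary.csv"),
    results = file.path(outDir, "regressions.csv"),
    ranking = file.path(outDir, "ranking.csv"),
    log = file.path(outDir, "log.txt"))
  utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  utils::write.csv(attr(metrics, "failures"), paths$failures,
                   row.names = FALSE)
  utils::write.csv(summ, paths$summary, row.names = FALSE)
  for (cat in names(cors)) {
    p <- file.path(outDir, sprintf("correlation_%s.csv", cat))
    utils::write.csv(as.data.frame(cors[[cat]]), p, row.names = TRUE)
    paths[[paste0("correlation_", cat)]] <- p
  }
  utils::write.csv(cmp$results, paths$results, row.names = FALSE)
  utils::write.csv(cmp$ranking, paths$ranking, row.names = FALSE)
  writeLines(c(log, warnings_seen), paths$log)

  invisible(list(metrics = metrics, summary = summ, correlations = cors,
                 results = cmp$results, ranking = cmp$ranking, set = set,
                 paths = paths))
}
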