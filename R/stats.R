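#' Pairwise Pearson correlations between metrics
#'
#' Pivots a metric table to a catchment-by-metric matrix for one land-use
#' category and returns the Pearson correlation matrix over catchments.
#' A metric with zero variance across catchments gets an undefined (NA)
#' row and column, with a warning, rather than a fabricated 0.
#'
#' @param table a metric table from [metricSuite()].
#' @param category land-use category name to correlate over.
#' @return A symmetric metric-by-metric correlation matrix with unit
#'   diagonal (where defined), ordered canonically.
#' @export
pearsonMatrix <- function(table, category) {
  sub <- table[table$category == category, , drop = FALSE]
  if (nrow(sub) == 0) stop("category not present in the metric table")
  wide <- reshape(sub[, c("catchment_id", "metric", "percent")],
                  idvar = "catchment_id", timevar = "metric",
                  direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^percent\\.", "", colnames(mat))
  ord <- intersect(metricNames(), colnames(mat))
  mat <- mat[, c(ord, setdiff(colnames(mat), ord)), drop = FALSE]
  if (nrow(mat) < 3) stop("need at least three catchments")
  v <- apply(mat, 2, stats::var, na.rm = TRUE)
  degen <- !is.finite(v) | v == 0
  if (any(degen))
    warning("zero-variance metric column(s): ",
            paste(colnames(mat)[degen], collapse = ", "),
            "; correlations reported as NA")
  cc <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  cc[degen, ] <- NA_real_
  cc[, degen] <- NA_real_
  diag(cc)[!degen] <- 1
  cc
}

#' Single-predictor least-squares fit
#'
#' Ordinary least squares of `y` on `x` with the single-predictor
#' identity `R^2 = cor(x, y)^2`, the standard error of the slope and a
#' two-sided t-test on the slope with n - 2 degrees of freedom. A
#' constant response is a valid degenerate case (slope 0, R^2 0); a
#' constant predictor is an error.
#'
#' @param x numeric predictor vector.
#' @param y numeric response vector, same length.
#' @return A list with elements `slope`, `intercept`, `se_slope`, `r2`,
#'   `p_value`, `n`.
#' @examples
#' olsFit(c(1, 2, 3), c(1, 2, 2))  # slope 0.5, r2 0.75
#' @export
olsFit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("insufficient observations")
  if (stats::var(x) == 0) stop("constant predictor")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))
  if (stats::var(y) == 0) {
    r2 <- 0; se <- 0; p <- 1
  } else {
    r2 <- sm$r.squared
    se <- sm$coefficients["x", "Std. Error"]
    p <- sm$coefficients["x", "Pr(>|t|)"]
    if (!is.finite(p)) p <- 0  # exact fit: zero residual variance
  }
  list(slope = unname(cf["x"]), intercept = unname(cf["(Intercept)"]),
       se_slope = se, r2 = r2, p_value = p, n = n)
}

#' Fit and rank all metrics as predictors of water quality
#'
#' Fits one single-predictor linear regression per combination of
#' water-quality parameter (response), landscape composition metric
#' (predictor) and land-use category, then ranks metrics by R^2 within
#' each (parameter, category) cell. Models with p below `alpha` are
#' flagged significant (no multiple-testing correction by default,
#' optionally Benjamini-Hochberg). Ranking ties break by the canonical
#' metric order, so output is fully deterministic.
#'
#' @param metrics a metric table from [metricSuite()].
#' @param wqp a `data.frame` with columns `catchment_id`, `parameter`,
#'   `value` (one row per catchment and parameter).
#' @param alpha significance level for flagging (default 0.05).
#' @param categories categories to analyse (default: all in `metrics`).
#' @param exclude optional `data.frame` with columns `catchment_id`,
#'   `parameter`: observations dropped before fitting (e.g. outlier
#'   sites for specific determinands).
#' @param dropParameters character vector of parameters excluded from the
#'   whole analysis.
#' @param adjust `"none"` (default) or `"BH"`: p-value adjustment applied
#'   across all reported fits before the significance flag.
#' @return A list with `results` (one row per fit: `wqp`, `category`,
#'   `metric`, `slope`, `se_slope`, `intercept`, `r2`, `p_value`, `n`,
#'   `significant`) and `ranking` (per `wqp` and `category`:
#'   `best_metric`, `best_r2`).
#' @export
compareMetrics <- function(metrics, wqp, alpha = 0.05, categories = NULL,
                           exclude = NULL, dropParameters = NULL,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("catchment_id", "parameter", "value") %in% names(wqp)))
  wqp$catchment_id <- as.character(wqp$catchment_id)
  metrics$catchment_id <- as.character(metrics$catchment_id)
  if (!is.null(dropParameters))
    wqp <- wqp[!wqp$parameter %in% dropParameters, , drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    key <- paste(wqp$catchment_id, wqp$parameter, sep = "\r")
    drop <- paste(as.character(exclude$catchment_id), exclude$parameter,
                  sep = "\r")
    wqp <- wqp[!key %in% drop, , drop = FALSE]
  }
  if (!length(intersect(metrics$catchment_id, wqp$catchment_id)))
    stop("no overlapping catchments between metric and water-quality tables")
  if (is.null(categories)) categories <- unique(metrics$category)
  metricOrder <- c(intersect(metricNames(), unique(metrics$metric)),
                   setdiff(unique(metrics$metric), metricNames()))

  rows <- list()
  for (p in unique(wqp$parameter)) {
    wp <- wqp[wqp$parameter == p, , drop = FALSE]
    for (cat in categories) {
      for (m in metricOrder) {
        sub <- metrics[metrics$metric == m & metrics$category == cat,
                       c("catchment_id", "percent"), drop = FALSE]
        j <- merge(sub, wp[, c("catchment_id", "value")],
                   by = "catchment_id")
        fit <- tryCatch(olsFit(j$percent, j$value),
                        error = function(e) NULL)
        if (is.null(fit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          wqp = p, category = cat, metric = m, slope = fit$slope,
          se_slope = fit$se_slope, intercept = fit$intercept, r2 = fit$r2,
          p_value = fit$p_value, n = fit$n, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no fittable (parameter, category, metric) cells")
  results <- do.call(rbind, rows)
  padj <- if (adjust == "BH") stats::p.adjust(results$p_value, "BH")
          else results$p_value
  results$significant <- padj < alpha

  ranking <- do.call(rbind, lapply(
    split(results, list(results$wqp, results$category), drop = TRUE),
    function(d) {
      ord <- order(-d$r2, match(d$metric, metricOrder))
      data.frame(wqp = d$wqp[1], category = d$category[1],
                 best_metric = d$metric[ord[1]], best_r2 = d$r2[ord[1]],
                 stringsAsFactors = FALSE)
    }))
  ranking <- ranking[order(ranking$wqp, ranking$category), , drop = FALSE]
  rownames(ranking) <- NULL
  rownames(results) <- NULL
  list(results = results, ranking = ranking)
}
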