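test_that("weight grids implement the multiplicative weighting", {
  fx <- eastPlane()
  uw <- buildWeightGrid(metricSpec("Unweighted"), mask = fx$mask)
  expect_equal(gridValues(uw), matrix(1, 3, 3))

  # stream cell (distance 0), slope 45 deg, A = 3: w = 1 * 45 * ln(3)
  ed <- gridLayer(matrix(0, 1, 1)); sl <- gridLayer(matrix(45, 1, 1))
  ac <- gridLayer(matrix(3, 1, 1)); mk <- gridLayer(matrix(1, 1, 1))
  w <- buildWeightGrid(metricSpec("Euclid-SlogA", "euclid", TRUE, "log"),
                       euclidDist = ed, slope = sl, accum = ac, mask = mk)
  expect_equal(gridValues(w)[1, 1], 45 * log(3), tolerance = 1e-12)
  expect_equal(45 * log(3), 49.4379, tolerance = 1e-4)

  # multiplicative zero on a flat cell under any slope metric
  sl0 <- gridLayer(matrix(0, 1, 1))
  w0 <- buildWeightGrid(metricSpec("Euclid-S", "euclid", TRUE),
                        euclidDist = ed, slope = sl0, mask = mk)
  expect_equal(gridValues(w0)[1, 1], 0)

  expect_error(buildWeightGrid(metricSpec("Euclid-A", "euclid", FALSE, "raw"),
                               euclidDist = ed,
                               accum = gridLayer(matrix(0.5, 1, 1)),
                               mask = mk),
               "self-inclusive")
  expect_error(buildWeightGrid(metricSpec("Flow", "flow"),
                               flowLen = gridLayer(matrix(NA_real_, 1, 1)),
                               mask = mk),
               "no flow-connected cells")
})

test_that("composition reproduces the hand-evaluated weighted proportions", {
  fx <- eastPlane()
  uw <- buildWeightGrid(metricSpec("Unweighted"), mask = fx$mask)
  expect_equal(composition(fx$landuse, uw),
               c(forest = 100 / 3, meadow = 200 / 3), tolerance = 1e-12)

  # Euclid weights by column: 1/11, 1/6, 1 -> forest (3/11)/(3/11+3/6+3)
  ed <- euclideanDistanceToStream(fx$stream)
  we <- buildWeightGrid(metricSpec("Euclid", "euclid"), euclidDist = ed,
                        mask = fx$mask)
  got <- composition(fx$landuse, we)
  expect_equal(got[["forest"]],
               100 * (3 / 11) / (3 / 11 + 3 / 6 + 3), tolerance = 1e-12)
  expect_equal(got[["forest"]], 7.229, tolerance = 1e-3)
  expect_equal(got[["meadow"]], 92.771, tolerance = 1e-4)

  # uniform category: 100% whatever the (positive) weights
  allForest <- landUseGrid(matrix(1L, 3, 3),
                           c("1" = "forest", "2" = "meadow"), 5)
  expect_equal(composition(allForest, we),
               c(forest = 100, meadow = 0), tolerance = 1e-12)

  expect_error(composition(fx$landuse,
                           gridLayer(matrix(0, 3, 3), 5)),
               "degenerate weights")
})

test_that("suite values equal the naive double-sum oracle and conserve 100%", {
  cfg <- smallConfig()
  set <- generateStudySet(cfg, seed = 301)
  cm <- set$catchments[[1]]
  tab <- set$metrics
  for (spec in canonicalMetrics()) {
    w <- buildWeightGrid(spec, cm$layers$edist, cm$layers$flen,
                         cm$layers$slope, cm$layers$accum, cm$mask)
    for (cat in c(forest = 1L, meadow = 2L)) {
      want <- oracleComposition(landUseCodes(cm$landuse), gridValues(w),
                                cat)
      got <- tab$percent[tab$metric == spec@name &
                         tab$category == names(which(c(forest = 1L,
                                                       meadow = 2L) == cat))]
      expect_equal(got, want, tolerance = 1e-9)
    }
    sums <- tapply(tab$percent, tab$metric, sum)
    expect_true(all(abs(sums - 100) < 1e-9))
  }
})

test_that("Euclid and Flow families coincide on the tilted-plane geometry", {
  fx <- eastPlane()
  tab <- metricSuite(fx$dem, fx$landuse, fx$stream, list(toy = fx$mask))
  wide <- tapply(tab$percent, list(tab$metric, tab$category), identity)
  for (v in c("", "-S", "-A", "-logA", "-SA", "-SlogA"))
    expect_equal(wide[paste0("Euclid", v), ], wide[paste0("Flow", v), ],
                 tolerance = 1e-12)
})

test_that("unweighted shares ignore the DEM and equal cell-count shares", {
  fx <- eastPlane()
  tab1 <- metricSuite(fx$dem, fx$landuse, fx$stream, list(a = fx$mask))
  bumpy <- gridLayer(gridValues(fx$dem) +
                       matrix(c(0, .2, 0, .3, 0, .1, 0, .2, 0), 3, 3), 5)
  tab2 <- metricSuite(bumpy, fx$landuse, fx$stream, list(a = fx$mask))
  u1 <- tab1[tab1$metric == "Unweighted", ]
  u2 <- tab2[tab2$metric == "Unweighted", ]
  expect_equal(u1$percent, u2$percent, tolerance = 1e-12)
  expect_equal(u1$percent[u1$category == "forest"], 100 / 3,
               tolerance = 1e-12)
})

test_that("weights are scale-free: rescaling slope units changes nothing", {
  cfg <- smallConfig()
  set <- generateStudySet(cfg, seed = 302)
  cm <- set$catchments[[1]]
  spec <- metricSpec("Euclid-SlogA", "euclid", TRUE, "log")
  w1 <- buildWeightGrid(spec, cm$layers$edist, cm$layers$flen,
                        cm$layers$slope, cm$layers$accum, cm$mask)
  slopeRad <- gridLayer(gridValues(cm$layers$slope) * pi / 180,
                        cellSize(cm$dem))
  w2 <- buildWeightGrid(spec, cm$layers$edist, cm$layers$flen,
                        slopeRad, cm$layers$accum, cm$mask)
  expect_equal(composition(cm$landuse, w1), composition(cm$landuse, w2),
               tolerance = 1e-9)
})

test_that("moving a forest patch toward the stream raises its Euclid share", {
  cs <- 5
  for (n in c(5, 7)) {
    stream <- matrix(0, n, n); stream[, n] <- 1
    dem <- t(sapply(1:n, function(r) (n:1)))
    prev <- -Inf
    for (pos in 1:(n - 1)) {
      codes <- matrix(2L, n, n)
      codes[ceiling(n / 2), pos] <- 1L
      lu <- landUseGrid(codes, c("1" = "forest", "2" = "meadow"), cs)
      ed <- euclideanDistanceToStream(gridLayer(stream, cs))
      w <- buildWeightGrid(metricSpec("Euclid", "euclid"),
                           euclidDist = ed,
                           mask = gridLayer(matrix(1, n, n), cs))
      share <- composition(lu, w)[["forest"]]
      expect_gt(share, prev)
      prev <- share
    }
  }
})

test_that("degenerate catchments are recorded, not fatal", {
  # an all-flat catchment has zero slope weights everywhere
  flat <- gridLayer(matrix(1, 4, 4), 5)
  stream <- gridLayer(matrix(c(rep(0, 12), rep(1, 4)), 4, 4), 5)
  lu <- landUseGrid(matrix(1L, 4, 4), c("1" = "forest", "2" = "meadow"), 5)
  mask <- gridLayer(matrix(1, 4, 4), 5)
  tab <- metricSuite(flat, lu, stream, list(f = mask))
  fails <- attr(tab, "failures")
  expect_true(all(c("Euclid-S", "Flow-S") %in% fails$metric))
  expect_true(any(grepl("degenerate", fails$error)))
  expect_true("Unweighted" %in% tab$metric)  # the rest of the table survives
})

test_that("summaries use the sample SD and canonical ordering", {
  tab <- data.frame(catchment_id = rep(c("a", "b"), each = 2),
                    metric = "Euclid",
                    category = rep(c("forest", "meadow"), 2),
                    percent = c(40, 60, 60, 40))
  s <- summarizeProportions(tab)
  expect_equal(s$mean, c(50, 50))
  expect_equal(s$sd, rep(sqrt(200), 2), tolerance = 1e-12)
  expect_equal(s$sd[1], 14.142, tolerance = 1e-3)

  same <- tab; same$percent <- c(40, 60, 40, 60)
  expect_equal(summarizeProportions(same)$sd, c(0, 0))

  set.seed(303)
  big <- expand.grid(catchment_id = sprintf("c%d", 1:6),
                     metric = metricNames(), category = "forest",
                     stringsAsFactors = FALSE)
  big$percent <- stats::runif(nrow(big), 0, 100)
  s2 <- summarizeProportions(big)
  expect_identical(s2$metric, metricNames())
  m <- big$percent[big$metric == "Flow-SA"]
  expect_equal(s2$mean[s2$metric == "Flow-SA"], mean(m))
  expect_equal(s2$sd[s2$metric == "Flow-SA"], sd(m))
})
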