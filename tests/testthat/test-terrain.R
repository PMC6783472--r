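test_that("depression filling raises pits to spill level and nothing else", {
  pit <- gridLayer(matrix(c(5, 5, 5, 5, 1, 5, 5, 5, 5), 3, 3, byrow = TRUE))
  out <- gridValues(fillDepressions(pit))
  expect_equal(out[2, 2], 5)
  expect_equal(out[-5], gridValues(pit)[-5])

  plane <- eastPlane()$dem
  expect_identical(gridValues(fillDepressions(plane)), gridValues(plane))

  expect_error(fillDepressions(gridLayer(matrix(NA_real_, 2, 2))),
               "empty DEM")
})

test_that("depression filling matches the exhaustive spill oracle and is idempotent", {
  set.seed(101)
  for (i in 1:20) {
    dem <- randomDem(10, 10)
    if (i %% 4 == 0) dem[sample(100, 5)] <- NA  # some nodata holes
    f1 <- gridValues(fillDepressions(gridLayer(dem)))
    expect_identical(f1, oracleFill(dem))
    f2 <- gridValues(fillDepressions(gridLayer(f1)))
    expect_identical(f2, f1)
    expect_true(all(f1 >= dem, na.rm = TRUE))
  }
})

test_that("Horn slope reproduces closed-form planar gradients", {
  nr <- 7; nc <- 7
  plane <- function(gx, cs) gridLayer(
    t(sapply(1:nr, function(r) -gx * (1:nc) * cs)), cellsize = cs)
  s45 <- gridValues(slopeGrid(plane(1, 1)))
  expect_equal(s45[2:(nr - 1), 2:(nc - 1)],
               matrix(45, nr - 2, nc - 2), tolerance = 1e-12)
  s05 <- gridValues(slopeGrid(plane(0.5, 5)))
  expect_lt(max(abs(s05[2:(nr - 1), 2:(nc - 1)] -
                    atan(0.5) * 180 / pi)), 1e-9)
  flat <- gridValues(slopeGrid(gridLayer(matrix(3, 5, 5))))
  expect_equal(flat, matrix(0, 5, 5))
  expect_equal(gridValues(slopeGrid(gridLayer(matrix(7, 1, 1)))),
               matrix(0, 1, 1))
})

test_that("D8 direction picks the steepest drop with documented flat handling", {
  fx <- eastPlane()
  d <- flowDirs(d8FlowDirection(fx$dem))
  expect_equal(d[, 1:2], matrix(1L, 3, 2))  # east
  expect_equal(d[, 3], rep(0L, 3))          # outlet column

  flat <- gridLayer(matrix(c(1, 1, NA), 1, 3))
  expect_equal(flowDirs(d8FlowDirection(flat))[1, ],
               c(1L, 0L, NA))               # drains east into nodata
})

test_that("D8 matches the brute-force steepest-descent oracle on random DEMs", {
  set.seed(102)
  for (i in 1:20) {
    dem <- oracleFill(randomDem(10, 10))
    d <- flowDirs(d8FlowDirection(gridLayer(dem)))
    o <- oracleSteepest(dem)
    sel <- !is.na(o)
    expect_identical(d[sel], o[sel])
    # acyclicity: walking from any cell never revisits one
    for (r in 1:10) for (c in 1:10) {
      p <- walkPath(d, r, c)
      keys <- vapply(p, function(x) x[1] * 100 + x[2], numeric(1))
      expect_false(anyDuplicated(keys) > 0)
    }
  }
})

test_that("flow accumulation is self-inclusive, conservative and oracle-exact", {
  fx <- eastPlane()
  fd <- d8FlowDirection(fx$dem)
  expect_equal(gridValues(flowAccumulation(fd)),
               matrix(rep(1:3, each = 3), 3, 3))
  expect_equal(gridValues(flowAccumulation(
    flowDirGrid(matrix(0L, 1, 1)))), matrix(1, 1, 1))

  off <- d8Offsets()
  set.seed(103)
  for (i in 1:20) {
    dem <- oracleFill(randomDem(10, 10))
    d <- flowDirs(d8FlowDirection(gridLayer(dem)))
    a <- gridValues(flowAccumulation(flowDirGrid(d)))
    expect_identical(a, oracleAccum(d))
    # conservation: A = 1 + sum of A over draining neighbours, grid-wide
    for (r in 1:10) for (c in 1:10) {
      up <- 0
      for (k in 1:8) {
        rr <- r + off$dr[k]; cc <- c + off$dc[k]
        if (rr < 1 || cc < 1 || rr > 10 || cc > 10) next
        opp <- ((k + 3) %% 8) + 1  # code pointing from neighbour to (r, c)
        if (isTRUE(d[rr, cc] == opp)) up <- up + a[rr, cc]
      }
      expect_equal(a[r, c], 1 + up)
    }
  }

  cyc <- matrix(NA_integer_, 2, 2); cyc[1, 1] <- 1L; cyc[1, 2] <- 5L
  expect_error(flowAccumulation(flowDirGrid(cyc)), "cyclic flow field")
})

test_that("Euclidean distance to stream is exact", {
  fx <- eastPlane()
  expect_equal(gridValues(euclideanDistanceToStream(fx$stream)),
               matrix(rep(c(10, 5, 0), each = 3), 3, 3))
  one <- matrix(0, 5, 5); one[1, 1] <- 1
  d <- gridValues(euclideanDistanceToStream(gridLayer(one)))
  expect_equal(d[4, 5], 5)  # 3-4-5 triangle in cell units
  set.seed(104)
  for (i in 1:10) {
    m <- matrix(as.numeric(stats::runif(225) < 0.08), 15, 15)
    if (!any(m == 1)) m[8, 8] <- 1
    got <- gridValues(euclideanDistanceToStream(gridLayer(m, cellsize = 3)))
    expect_identical(got, oracleEuclid(m, 3))
  }
  expect_error(euclideanDistanceToStream(gridLayer(matrix(0, 3, 3))),
               "empty stream network")
})

test_that("flow length sums the along-path steps to the first stream cell", {
  fx <- eastPlane()
  fd <- d8FlowDirection(fx$dem)
  expect_equal(gridValues(flowLengthToStream(fd, fx$stream)),
               matrix(rep(c(10, 5, 0), each = 3), 3, 3))

  # one diagonal then one cardinal step, cellsize 5
  d <- matrix(NA_integer_, 3, 3)
  d[1, 1] <- 2L; d[2, 2] <- 1L; d[2, 3] <- 0L
  st <- matrix(0, 3, 3); st[2, 3] <- 1
  fl <- gridValues(flowLengthToStream(flowDirGrid(d, cellsize = 5),
                                      gridLayer(st, cellsize = 5)))
  expect_equal(fl[1, 1], 5 * sqrt(2) + 5)

  set.seed(105)
  for (i in 1:20) {
    dem <- oracleFill(randomDem(10, 10))
    dd <- flowDirs(d8FlowDirection(gridLayer(dem)))
    st <- matrix(as.numeric(stats::runif(100) < 0.1), 10, 10)
    got <- gridValues(flowLengthToStream(flowDirGrid(dd, cellsize = 2),
                                         gridLayer(st, cellsize = 2)))
    expect_equal(got, oracleFlowLen(dd, st, 2))
  }
})

test_that("on a single-tilt plane Euclidean and flow distance coincide", {
  fx <- eastPlane()
  fd <- d8FlowDirection(fx$dem)
  expect_identical(gridValues(flowLengthToStream(fd, fx$stream)),
                   gridValues(euclideanDistanceToStream(fx$stream)))
})

test_that("catchment delineation matches per-cell path membership", {
  fx <- eastPlane()
  fd <- d8FlowDirection(fx$dem)
  m <- gridValues(delineateCatchment(fd, c(2, 3)))
  expect_equal(m, matrix(c(0, 0, 0, 1, 1, 1, 0, 0, 0), 3, 3, byrow = TRUE))
  expect_equal(sum(gridValues(delineateCatchment(fd, c(1, 1)))), 1)

  set.seed(106)
  for (i in 1:20) {
    dem <- oracleFill(randomDem(10, 10))
    dd <- flowDirs(d8FlowDirection(gridLayer(dem)))
    outlet <- c(sample(10, 1), sample(10, 1))
    got <- gridValues(delineateCatchment(flowDirGrid(dd), outlet))
    expect_identical(got, oracleDelineate(dd, outlet))
  }

  hole <- matrix(c(1, NA, 1, 1), 2, 2)
  fdh <- d8FlowDirection(gridLayer(hole))
  expect_error(delineateCatchment(fdh, c(2, 1)), "defined cell")
})
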