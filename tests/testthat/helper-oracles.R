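# Brute-force oracles for the terrain kernels, deliberately naive and
# independent of the package implementation: plain R loops, no shared
# helpers beyond the neighbour table.

.nbr <- data.frame(code = 1:8,
                   dr = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L),
                   dc = c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L),
                   mult = c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2)))

# raise every cell to the minimal spill elevation over all 8-connected
# paths to the edge (or to a nodata cell), by fixed-point relaxation
oracleFill <- function(dem) {
  nr <- nrow(dem); nc <- ncol(dem)
  f <- matrix(Inf, nr, nc)
  exit <- function(r, c) {
    if (r == 1 || c == 1 || r == nr || c == nc) return(TRUE)
    for (k in 1:8)
      if (is.na(dem[r + .nbr$dr[k], c + .nbr$dc[k]])) return(TRUE)
    FALSE
  }
  for (r in 1:nr) for (c in 1:nc)
    if (!is.na(dem[r, c]) && exit(r, c)) f[r, c] <- dem[r, c]
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) {
      if (is.na(dem[r, c]) || f[r, c] == dem[r, c]) next
      for (k in 1:8) {
        rr <- r + .nbr$dr[k]; cc <- c + .nbr$dc[k]
        if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
        if (is.na(dem[rr, cc]) || !is.finite(f[rr, cc])) next
        cand <- max(dem[r, c], f[rr, cc])
        if (cand < f[r, c]) { f[r, c] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  f[is.na(dem)] <- NA_real_
  f
}

# steepest-descent code per cell, only where some in-grid drop is
# strictly positive; NA elsewhere (flats are implementation-defined)
oracleSteepest <- function(dem, cellsize = 1) {
  nr <- nrow(dem); nc <- ncol(dem)
  out <- matrix(NA_integer_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(dem[r, c])) next
    best <- 0; bestk <- NA_integer_
    for (k in 1:8) {
      rr <- r + .nbr$dr[k]; cc <- c + .nbr$dc[k]
      if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
      if (is.na(dem[rr, cc])) next
      g <- (dem[r, c] - dem[rr, cc]) / (.nbr$mult[k] * cellsize)
      if (g > best) { best <- g; bestk <- k }
    }
    out[r, c] <- bestk
  }
  out
}

# per-cell downslope walk; returns the sequence of (r, c) visited,
# starting at the cell itself, ending before leaving the grid
walkPath <- function(dirs, r, c) {
  path <- list()
  repeat {
    path[[length(path) + 1L]] <- c(r, c)
    d <- dirs[r, c]
    if (is.na(d) || d == 0) break
    r <- r + .nbr$dr[d]; c <- c + .nbr$dc[d]
    if (r < 1 || c < 1 || r > nrow(dirs) || c > ncol(dirs)) break
    if (is.na(dirs[r, c])) break
  }
  path
}

oracleAccum <- function(dirs) {
  nr <- nrow(dirs); nc <- ncol(dirs)
  a <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(dirs[r, c])) { a[r, c] <- NA_real_; next }
    for (p in walkPath(dirs, r, c)) a[p[1], p[2]] <- a[p[1], p[2]] + 1
  }
  a
}

oracleFlowLen <- function(dirs, stream, cellsize) {
  nr <- nrow(dirs); nc <- ncol(dirs)
  out <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(dirs[r, c])) next
    len <- 0; rr <- r; cc <- c; hit <- FALSE
    repeat {
      if (isTRUE(stream[rr, cc] != 0)) { hit <- TRUE; break }
      d <- dirs[rr, cc]
      if (is.na(d) || d == 0) break
      len <- len + .nbr$mult[d] * cellsize
      rr <- rr + .nbr$dr[d]; cc <- cc + .nbr$dc[d]
      if (rr < 1 || cc < 1 || rr > nr || cc > nc || is.na(dirs[rr, cc]))
        break
    }
    if (hit) out[r, c] <- len
  }
  out
}

oracleDelineate <- function(dirs, outlet) {
  nr <- nrow(dirs); nc <- ncol(dirs)
  m <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (is.na(dirs[r, c])) { m[r, c] <- NA_real_; next }
    for (p in walkPath(dirs, r, c))
      if (p[1] == outlet[1] && p[2] == outlet[2]) { m[r, c] <- 1; break }
  }
  m
}

oracleEuclid <- function(stream, cellsize) {
  nr <- nrow(stream); nc <- ncol(stream)
  sc <- which(stream != 0 & !is.na(stream), arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    out[r, c] <- sqrt(min((r - sc[, 1])^2 + (c - sc[, 2])^2)) * cellsize
  out
}

# naive evaluation of one weighted composition by explicit double loop
oracleComposition <- function(codes, w, code) {
  num <- 0; den <- 0
  for (r in seq_len(nrow(w))) for (c in seq_len(ncol(w))) {
    if (is.na(w[r, c])) next
    den <- den + w[r, c]
    if (!is.na(codes[r, c]) && codes[r, c] == code)
      num <- num + w[r, c]
  }
  100 * num / den
}

randomDem <- function(nr = 10, nc = 10, relief = 5)
  matrix(stats::runif(nr * nc, 0, relief), nr, nc)
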