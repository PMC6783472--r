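// Raster terrain kernels: priority-flood depression filling, D8 flow
// direction with flat resolution, flow accumulation, flow length to stream,
// watershed delineation and a Euclidean distance transform.
//
// Grids are R numeric matrices with NA as the in-memory nodata sentinel,
// row 1 = northern edge. Direction codes follow the fixed neighbor scan
// order 1=E, 2=SE, 3=S, 4=SW, 5=W, 6=NW, 7=N, 8=NE; 0 marks an outlet
// (flow leaves the grid or enters nodata); NA marks an undefined cell.

#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};
// distance multiplier per direction (1 cardinal, sqrt(2) diagonal)
static const double DMUL[8] = {1.0, M_SQRT2, 1.0, M_SQRT2,
                               1.0, M_SQRT2, 1.0, M_SQRT2};

struct PfCell {
  double elev;
  std::int64_t order; // insertion counter: deterministic FIFO tie-break
  int r, c;
};
struct PfCmp {
  bool operator()(const PfCell& a, const PfCell& b) const {
    if (a.elev != b.elev) return a.elev > b.elev; // min-heap on elevation
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
NumericMatrix cpp_fill_depressions(NumericMatrix dem) {
  const int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix out(nr, nc);
  std::vector<bool> closed((size_t)nr * nc, false);
  std::priority_queue<PfCell, std::vector<PfCell>, PfCmp> open;
  std::int64_t counter = 0;
  int ndef = 0;

  auto idx = [nc](int r, int c) { return (size_t)r * nc + c; };

  // seed: border cells and cells adjacent to nodata (water can exit there)
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double z = dem(r, c);
      out(r, c) = z;
      if (NumericMatrix::is_na(z)) {
        closed[idx(r, c)] = true;
        continue;
      }
      ++ndef;
      bool edge = (r == 0 || c == 0 || r == nr - 1 || c == nc - 1);
      if (!edge) {
        for (int k = 0; k < 8 && !edge; ++k) {
          int rr = r + DR[k], cc = c + DC[k];
          if (NumericMatrix::is_na(dem(rr, cc))) edge = true;
        }
      }
      if (edge) {
        open.push({z, counter++, r, c});
        closed[idx(r, c)] = true;
      }
    }
  }
  if (ndef == 0) stop("empty DEM");

  while (!open.empty()) {
    PfCell cell = open.top();
    open.pop();
    for (int k = 0; k < 8; ++k) {
      int rr = cell.r + DR[k], cc = cell.c + DC[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      if (closed[idx(rr, cc)]) continue;
      closed[idx(rr, cc)] = true;
      double z = dem(rr, cc);
      double spill = (z < cell.elev) ? cell.elev : z; // raise to spill level
      out(rr, cc) = spill;
      open.push({spill, counter++, rr, cc});
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_d8_flow_direction(NumericMatrix dem) {
  const int nr = dem.nrow(), nc = dem.ncol();
  IntegerMatrix dirs(nr, nc);
  std::fill(dirs.begin(), dirs.end(), NA_INTEGER);

  auto defined = [&](int r, int c) {
    return r >= 0 && c >= 0 && r < nr && c < nc &&
           !NumericMatrix::is_na(dem(r, c));
  };

  // pass 1: steepest positive drop/distance; ties by scan order E..NE
  std::vector<std::pair<int, int>> flats;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!defined(r, c)) continue;
      double best = 0.0;
      int bestk = -1;
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR[k], cc = c + DC[k];
        if (!defined(rr, cc)) continue;
        double grad = (dem(r, c) - dem(rr, cc)) / DMUL[k];
        if (grad > best) {
          best = grad;
          bestk = k;
        }
      }
      if (bestk >= 0)
        dirs(r, c) = bestk + 1;
      else
        flats.push_back({r, c});
    }
  }

  // pass 2: flat cells adjacent to nodata drain into it (outlet seeds)
  std::deque<std::pair<int, int>> bfs;
  std::vector<char> resolved((size_t)nr * nc, 0);
  auto idx = [nc](int r, int c) { return (size_t)r * nc + c; };
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (dirs(r, c) != NA_INTEGER) resolved[idx(r, c)] = 1;

  std::vector<std::pair<int, int>> pending;
  for (auto& f : flats) {
    bool na_adj = false;
    for (int k = 0; k < 8 && !na_adj; ++k) {
      int rr = f.first + DR[k], cc = f.second + DC[k];
      if (rr >= 0 && cc >= 0 && rr < nr && cc < nc &&
          NumericMatrix::is_na(dem(rr, cc)))
        na_adj = true;
    }
    if (na_adj) {
      dirs(f.first, f.second) = 0;
      resolved[idx(f.first, f.second)] = 1;
    } else {
      pending.push_back(f);
    }
  }

  // BFS flat resolution toward nearest resolved equal-elevation cell;
  // flats with no internal drainage exit at their grid-border members
  auto run_bfs = [&](std::deque<std::pair<int, int>>& q) {
    while (!q.empty()) {
      auto cur = q.front();
      q.pop_front();
      for (int k = 0; k < 8; ++k) {
        int rr = cur.first + DR[k], cc = cur.second + DC[k];
        if (!defined(rr, cc) || resolved[idx(rr, cc)]) continue;
        if (dem(rr, cc) != dem(cur.first, cur.second)) continue;
        // neighbor drains toward cur: direction is the opposite code
        dirs(rr, cc) = ((k + 4) % 8) + 1;
        resolved[idx(rr, cc)] = 1;
        q.push_back({rr, cc});
      }
    }
  };

  // seed initial BFS from every resolved cell (deterministic row-major order)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (resolved[idx(r, c)]) bfs.push_back({r, c});
  run_bfs(bfs);

  for (;;) {
    std::deque<std::pair<int, int>> q;
    bool any_unresolved = false;
    for (auto& f : pending) {
      if (resolved[idx(f.first, f.second)]) continue;
      any_unresolved = true;
      bool border = (f.first == 0 || f.second == 0 || f.first == nr - 1 ||
                     f.second == nc - 1);
      if (border) {
        dirs(f.first, f.second) = 0;
        resolved[idx(f.first, f.second)] = 1;
        q.push_back(f);
      }
    }
    if (!any_unresolved) break;
    if (q.empty())
      stop("unresolvable flat region (DEM not depression-filled?)");
    run_bfs(q);
  }
  return dirs;
}

// [[Rcpp::export]]
NumericMatrix cpp_flow_accumulation(IntegerMatrix dirs) {
  const int nr = dirs.nrow(), nc = dirs.ncol();
  NumericMatrix acc(nr, nc);
  std::vector<int> indeg((size_t)nr * nc, 0);
  auto idx = [nc](int r, int c) { return (size_t)r * nc + c; };

  int ndef = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int d = dirs(r, c);
      if (d == NA_INTEGER) {
        acc(r, c) = NA_REAL;
        continue;
      }
      ++ndef;
      acc(r, c) = 1.0; // self-inclusive count
      if (d >= 1 && d <= 8) {
        int rr = r + DR[d - 1], cc = c + DC[d - 1];
        if (rr >= 0 && cc >= 0 && rr < nr && cc < nc &&
            dirs(rr, cc) != NA_INTEGER)
          indeg[idx(rr, cc)]++;
      }
    }
  }

  std::deque<std::pair<int, int>> q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (dirs(r, c) != NA_INTEGER && indeg[idx(r, c)] == 0) q.push_back({r, c});

  int processed = 0;
  while (!q.empty()) {
    auto cur = q.front();
    q.pop_front();
    ++processed;
    int d = dirs(cur.first, cur.second);
    if (d >= 1 && d <= 8) {
      int rr = cur.first + DR[d - 1], cc = cur.second + DC[d - 1];
      if (rr >= 0 && cc >= 0 && rr < nr && cc < nc &&
          dirs(rr, cc) != NA_INTEGER) {
        acc(rr, cc) += acc(cur.first, cur.second);
        if (--indeg[idx(rr, cc)] == 0) q.push_back({rr, cc});
      }
    }
  }
  if (processed != ndef) stop("cyclic flow field");
  return acc;
}

// [[Rcpp::export]]
NumericMatrix cpp_flow_length(IntegerMatrix dirs, LogicalMatrix stream,
                              double cellsize) {
  const int nr = dirs.nrow(), nc = dirs.ncol();
  NumericMatrix len(nr, nc);
  // status: 0 unknown, 1 on current path, 2 done
  std::vector<char> status((size_t)nr * nc, 0);
  auto idx = [nc](int r, int c) { return (size_t)r * nc + c; };
  auto is_stream = [&](int r, int c) {
    int v = stream(r, c);
    return v != NA_LOGICAL && v != 0;
  };

  std::fill(len.begin(), len.end(), NA_REAL);
  std::vector<int> path; // flattened indices of the walk

  for (int r0 = 0; r0 < nr; ++r0) {
    for (int c0 = 0; c0 < nc; ++c0) {
      if (dirs(r0, c0) == NA_INTEGER || status[idx(r0, c0)] == 2) continue;
      path.clear();
      int r = r0, c = c0;
      double tail = NA_REAL; // length at the cell terminating the walk
      for (;;) {
        size_t i = idx(r, c);
        if (status[i] == 2) { tail = len(r, c); break; }
        if (status[i] == 1) stop("cyclic flow field");
        if (is_stream(r, c)) {
          len(r, c) = 0.0;
          status[i] = 2;
          tail = 0.0;
          break;
        }
        int d = dirs(r, c);
        if (d == 0 || d == NA_INTEGER) {
          // terminates off-grid without meeting the stream
          len(r, c) = NA_REAL;
          status[i] = 2;
          tail = NA_REAL;
          break;
        }
        status[i] = 1;
        path.push_back((int)i);
        r += DR[d - 1];
        c += DC[d - 1];
        if (r < 0 || c < 0 || r >= nr || c >= nc ||
            dirs(r, c) == NA_INTEGER) {
          tail = NA_REAL; // stepped off the defined grid
          break;
        }
      }
      // unwind, adding one step length per cell
      for (int k = (int)path.size() - 1; k >= 0; --k) {
        int i = path[k];
        int pr = i / nc, pc = i % nc;
        if (ISNAN(tail)) {
          len(pr, pc) = NA_REAL;
        } else {
          int d = dirs(pr, pc);
          tail += cellsize * DMUL[d - 1];
          len(pr, pc) = tail;
        }
        status[i] = 2;
      }
    }
  }
  return len;
}

// [[Rcpp::export]]
IntegerMatrix cpp_delineate(IntegerMatrix dirs, int outlet_r, int outlet_c) {
  const int nr = dirs.nrow(), nc = dirs.ncol();
  if (outlet_r < 0 || outlet_c < 0 || outlet_r >= nr || outlet_c >= nc ||
      dirs(outlet_r, outlet_c) == NA_INTEGER)
    stop("outlet is not a defined cell");
  IntegerMatrix mask(nr, nc);
  std::deque<std::pair<int, int>> q;
  mask(outlet_r, outlet_c) = 1;
  q.push_back({outlet_r, outlet_c});
  while (!q.empty()) {
    auto cur = q.front();
    q.pop_front();
    for (int k = 0; k < 8; ++k) {
      int rr = cur.first + DR[k], cc = cur.second + DC[k];
      if (rr < 0 || cc < 0 || rr >= nr || cc >= nc) continue;
      if (mask(rr, cc)) continue;
      int d = dirs(rr, cc);
      if (d == NA_INTEGER || d < 1 || d > 8) continue;
      // does (rr, cc) drain into cur? its direction is opposite of k
      if (d == ((k + 4) % 8) + 1) {
        mask(rr, cc) = 1;
        q.push_back({rr, cc});
      }
    }
  }
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (dirs(r, c) == NA_INTEGER) mask(r, c) = NA_INTEGER;
  return mask;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher 2012,
// lower-envelope-of-parabolas); exact for integer-valued f.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n) {
  static const double BIG = 1e30;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_euclid_dist(LogicalMatrix stream, double cellsize) {
  const int nr = stream.nrow(), nc = stream.ncol();
  const double FAR = 1e15; // finite "no source" sentinel; q^2 << FAR
  bool any_stream = false;
  NumericMatrix sq(nr, nc);
  // pass 1: per column, squared distance to the nearest stream cell in
  // that column
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int v = stream(r, c);
      bool s = (v != NA_LOGICAL && v != 0);
      if (s) any_stream = true;
      f[r] = s ? 0.0 : FAR;
    }
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) sq(r, c) = d[r];
  }
  if (!any_stream) stop("empty stream network");
  // pass 2: per row over the column results
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = sq(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) sq(r, c) = std::sqrt(d[c]) * cellsize;
  }
  return sq;
}
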