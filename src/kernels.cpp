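#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared distance, in pixel units, from every pixel to the nearest pixel
// where mask is FALSE. Pixels that are FALSE get 0. Uses a large finite
// sentinel instead of +Inf so the parabola arithmetic stays well-defined;
// results are exact (small integers) for every pixel with a reachable
// outside pixel, and >= BIG when none exists (all-TRUE input; callers
// reject that case up front).
// [[Rcpp::export]]
NumericMatrix cpp_sq_edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  const double BIG = 1e18;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // pass 1: columns
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? BIG : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // pass 2: rows
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = d[j];
  }
  return out;
}

// ---- connected component labeling, 2D (conn 4/8) and 3D (conn 6/26) ----

// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix fg, int connectivity) {
  int nr = fg.nrow(), nc = fg.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dy8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dx8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      if (!fg(i, j) || lab(i, j) != 0) continue;
      next++;
      stack.clear();
      stack.push_back(i + nr * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nnb; k++) {
          int qi = pi + dy8[k], qj = pj + dx8[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (fg(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + nr * qj);
          }
        }
      }
    }
  }
  return lab;
}

// fg is a logical array laid out column-major with dim = c(nz, ny, nx).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector fg, IntegerVector dim, int connectivity) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> offz, offy, offx;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        int manh = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && manh != 1) continue;
        offz.push_back(dz); offy.push_back(dy); offx.push_back(dx);
      }
  int nnb = offz.size();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t p = 0; p < n; p++) {
    if (!fg[p] || lab[p] != 0) continue;
    next++;
    stack.clear(); stack.push_back(p); lab[p] = next;
    while (!stack.empty()) {
      R_xlen_t q = stack.back(); stack.pop_back();
      int z = q % nz, rem = q / nz;
      int y = rem % ny, x = rem / ny;
      for (int k = 0; k < nnb; k++) {
        int z2 = z + offz[k], y2 = y + offy[k], x2 = x + offx[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
        R_xlen_t q2 = z2 + (R_xlen_t)nz * (y2 + (R_xlen_t)ny * x2);
        if (fg[q2] && lab[q2] == 0) { lab[q2] = next; stack.push_back(q2); }
      }
    }
  }
  lab.attr("dim") = dim;
  lab.attr("n_components") = next;
  return lab;
}

// ---- point in polygon (even-odd ray casting) ----

// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  int n = px.size(), m = vx.size();
  LogicalVector inside(n);
  for (int i = 0; i < n; i++) {
    double x = px[i], y = py[i];
    bool in = false;
    for (int j = 0, k = m - 1; j < m; k = j++) {
      if (((vy[j] > y) != (vy[k] > y)) &&
          (x < (vx[k] - vx[j]) * (y - vy[j]) / (vy[k] - vy[j]) + vx[j]))
        in = !in;
    }
    inside[i] = in;
  }
  return inside;
}

// ---- outer boundary tracing (Moore neighborhood, clockwise) ----
// Returns an n x 2 matrix of 0-based (x, y) pixel coordinates of the outer
// contour of the foreground, starting from the topmost-leftmost pixel.
// Assumes a single connected component (caller selects it).
// [[Rcpp::export]]
IntegerMatrix cpp_trace_boundary(LogicalMatrix fg) {
  int nr = fg.nrow(), nc = fg.ncol();
  int si = -1, sj = -1;
  for (int i = 0; i < nr && si < 0; i++)
    for (int j = 0; j < nc; j++)
      if (fg(i, j)) { si = i; sj = j; break; }
  if (si < 0) stop("empty mask");
  // Moore neighborhood in clockwise order starting from W
  const int di[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<int> bi, bj;
  int ci = si, cj = sj;
  int backtrack = 0;  // came from W initially
  bi.push_back(ci); bj.push_back(cj);
  int start_i = ci, start_j = cj;
  int first_next_i = -1, first_next_j = -1;
  int guard = 0, guard_max = 8 * nr * nc + 8;
  while (guard++ < guard_max) {
    bool moved = false;
    for (int k = 0; k < 8; k++) {
      int dir = (backtrack + k) % 8;
      int ni = ci + di[dir], nj = cj + dj[dir];
      if (ni >= 0 && ni < nr && nj >= 0 && nj < nc && fg(ni, nj)) {
        // new backtrack: direction pointing to the previous position,
        // advanced by one clockwise step
        int prev_dir = (dir + 4) % 8;       // from neighbor back to current
        backtrack = (prev_dir + 1) % 8;
        ci = ni; cj = nj;
        moved = true;
        break;
      }
    }
    if (!moved) break;  // isolated pixel
    if (first_next_i < 0) { first_next_i = ci; first_next_j = cj; }
    else if (ci == start_i && cj == start_j) {
      // Jacob's stopping criterion: stop when we re-enter the start pixel
      break;
    }
    bi.push_back(ci); bj.push_back(cj);
  }
  // drop duplicated closing vertex if present
  int n = bi.size();
  if (n > 1 && bi[n - 1] == bi[0] && bj[n - 1] == bj[0]) n--;
  IntegerMatrix out(n, 2);
  for (int t = 0; t < n; t++) { out(t, 0) = bj[t]; out(t, 1) = bi[t]; }  // (x, y)
  return out;
}
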