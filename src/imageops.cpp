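#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Distance from each true pixel of `fg` to the nearest false pixel.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericMatrix edt_cpp(const LogicalMatrix& fg) {
  const int H = fg.nrow(), W = fg.ncol();
  const double INF = 1e18;
  NumericMatrix sq(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) sq(i, j) = fg(i, j) ? INF : 0.0;
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int j = 0; j < W; ++j) {           // columns
    for (int i = 0; i < H; ++i) f[i] = sq(i, j);
    dt1d(f, d, H);
    for (int i = 0; i < H; ++i) sq(i, j) = d[i];
  }
  for (int i = 0; i < H; ++i) {           // rows
    for (int j = 0; j < W; ++j) f[j] = sq(i, j);
    dt1d(f, d, W);
    for (int j = 0; j < W; ++j) sq(i, j) = d[j];
  }
  // pixels beyond the image border count as background
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      double b = std::min(std::min(i + 1, H - i), std::min(j + 1, W - j));
      double v = std::min(sq(i, j), b * b);
      sq(i, j) = std::sqrt(v);
    }
  return sq;
}

// ---- connected component labelling (BFS) ----

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(const LogicalMatrix& fg, int connectivity = 4) {
  const int H = fg.nrow(), W = fg.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> qi, qj;
  const int dx4[4] = {1, -1, 0, 0}, dy4[4] = {0, 0, 1, -1};
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1},
            dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int* dx = connectivity == 8 ? dx8 : dx4;
  const int* dy = connectivity == 8 ? dy8 : dy4;
  const int nd = connectivity == 8 ? 8 : 4;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!fg(i0, j0) || lab(i0, j0)) continue;
      lab(i0, j0) = ++next;
      qi.clear(); qj.clear();
      qi.push_back(i0); qj.push_back(j0);
      size_t head = 0;
      while (head < qi.size()) {
        int i = qi[head], j = qj[head];
        ++head;
        for (int k = 0; k < nd; ++k) {
          int ii = i + dy[k], jj = j + dx[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (fg(ii, jj) && !lab(ii, jj)) {
            lab(ii, jj) = next;
            qi.push_back(ii); qj.push_back(jj);
          }
        }
      }
    }
  return lab;
}

// ---- marker-based watershed on a height map (flood from high to low) ----

struct WsPix {
  double h;
  long order;
  int i, j, from;
};
struct WsCmp {
  bool operator()(const WsPix& a, const WsPix& b) const {
    if (a.h != b.h) return a.h < b.h;   // max-heap on height
    return a.order > b.order;           // FIFO among equal heights
  }
};

// [[Rcpp::export(name = ".watershed_cpp")]]
IntegerMatrix watershed_cpp(const NumericMatrix& height,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  const int H = height.nrow(), W = height.ncol();
  IntegerMatrix lab(H, W);
  std::priority_queue<WsPix, std::vector<WsPix>, WsCmp> pq;
  long order = 0;
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (markers(i, j) > 0 && mask(i, j)) lab(i, j) = markers(i, j);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j) > 0)
        for (int k = 0; k < 4; ++k) {
          int ii = i + dy[k], jj = j + dx[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0)
            pq.push({height(ii, jj), order++, ii, jj, lab(i, j)});
        }
  while (!pq.empty()) {
    WsPix p = pq.top();
    pq.pop();
    if (lab(p.i, p.j) != 0) continue;
    lab(p.i, p.j) = p.from;
    for (int k = 0; k < 4; ++k) {
      int ii = p.i + dy[k], jj = p.j + dx[k];
      if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
      if (mask(ii, jj) && lab(ii, jj) == 0)
        pq.push({height(ii, jj), order++, ii, jj, p.from});
    }
  }
  return lab;
}

// ---- constrained label propagation (cytoplasm ring growth) ----
// Grows labels outward one 4-connected pixel per round, for `rounds` rounds,
// only into pixels where `allowed` is true. Ties go to the lowest label.

// [[Rcpp::export(name = ".propagate_labels_cpp")]]
IntegerMatrix propagate_labels_cpp(const IntegerMatrix& labels,
                                   const LogicalMatrix& allowed, int rounds) {
  const int H = labels.nrow(), W = labels.ncol();
  IntegerMatrix cur = clone(labels);
  const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
  for (int r = 0; r < rounds; ++r) {
    IntegerMatrix nxt = clone(cur);
    bool changed = false;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        if (cur(i, j) != 0 || !allowed(i, j)) continue;
        int best = 0;
        for (int k = 0; k < 4; ++k) {
          int ii = i + dy[k], jj = j + dx[k];
          if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
          int l = cur(ii, jj);
          if (l > 0 && (best == 0 || l < best)) best = l;
        }
        if (best > 0) { nxt(i, j) = best; changed = true; }
      }
    cur = nxt;
    if (!changed) break;
  }
  return cur;
}
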