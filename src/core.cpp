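#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Grids are 3D, column-major: idx = i1 + n1*(i2 + n2*i3), dims (n1,n2,n3).
// Convention elsewhere in the package: (z, y, x).

static inline long vidx(int i, int j, int k, int n1, int n2) {
  return (long)i + (long)n1 * ((long)j + (long)n2 * (long)k);
}

// ---------------------------------------------------------------------------
// 1D squared-distance transform (lower envelope of parabolas), grid spacing s.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq = q * s, si, sv;
    while (true) {
      sv = v[k] * s;
      si = ((f[q] + sq * sq) - (f[v[k]] + sv * sv)) / (2.0 * sq - 2.0 * sv);
      if (si <= z[k] && k > 0) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = si;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double sq = q * s;
    while (z[k + 1] < sq) ++k;
    double dv = sq - v[k] * s;
    d[q] = dv * dv + f[v[k]];
  }
}

// Squared Euclidean distance (physical units via `spacing`) from every true
// voxel of `mask` to the nearest false voxel; 0 on background.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  long n = (long)n1 * n2 * n3;
  NumericVector out(n);
  const double INF = 1e30;
  for (long i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // axis 1
  f.resize(n1); d.resize(n1);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      for (int i = 0; i < n1; ++i) f[i] = out[vidx(i, j, k, n1, n2)];
      dt1d(f, d, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) out[vidx(i, j, k, n1, n2)] = d[i];
    }
  // axis 2
  f.resize(n2); d.resize(n2);
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      for (int j = 0; j < n2; ++j) f[j] = out[vidx(i, j, k, n1, n2)];
      dt1d(f, d, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) out[vidx(i, j, k, n1, n2)] = d[j];
    }
  // axis 3
  f.resize(n3); d.resize(n3);
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      for (int k = 0; k < n3; ++k) f[k] = out[vidx(i, j, k, n1, n2)];
      dt1d(f, d, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) out[vidx(i, j, k, n1, n2)] = d[k];
    }
  return out;
}

// 6-connected component labelling of a binary 3D mask.
// [[Rcpp::export]]
IntegerVector cpp_cclabel3d(LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  long n = (long)n1 * n2 * n3;
  IntegerVector lab(n);
  std::vector<long> stack;
  int next = 0;
  for (long s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % n1);
      long r = cur / n1;
      int j = (int)(r % n2);
      int k = (int)(r / n2);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        long t = vidx(ii, jj, kk, n1, n2);
        if (mask[t] && lab[t] == 0) {
          lab[t] = next;
          stack.push_back(t);
        }
      }
    }
  }
  return lab;
}

struct WsEntry {
  double v;
  long ord;
  long idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.v != b.v) return a.v > b.v;  // min-heap on priority value
    return a.ord > b.ord;              // FIFO tie-break => determinism
  }
};

// Marker-imposed watershed by priority flooding of `priority` (typically a
// gradient magnitude), restricted to `mask`. Each seed label grows into the
// mask; background is never flooded.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector priority, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  long n = (long)n1 * n2 * n3;
  IntegerVector lab(n);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long ord = 0;
  for (long s = 0; s < n; ++s) {
    if (seeds[s] > 0 && mask[s]) {
      lab[s] = seeds[s];
      pq.push({priority[s], ord++, s});
    }
  }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    long cur = e.idx;
    int labc = lab[cur];
    int i = (int)(cur % n1);
    long r = cur / n1;
    int j = (int)(r % n2);
    int k = (int)(r / n2);
    for (int q = 0; q < 6; ++q) {
      int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      long t = vidx(ii, jj, kk, n1, n2);
      if (mask[t] && lab[t] == 0) {
        lab[t] = labc;
        pq.push({priority[t], ord++, t});
      }
    }
  }
  return lab;
}

// Convolve every column of `m` along rows with an odd-length kernel,
// reflect (edge-replicate) padding. Used for separable Gaussian and box
// filters on 3D volumes via axis permutation.
// [[Rcpp::export]]
NumericMatrix cpp_conv1_first(NumericMatrix m, NumericVector kernel) {
  int n = m.nrow(), p = m.ncol(), kl = kernel.size();
  int r = (kl - 1) / 2;
  NumericMatrix out(n, p);
  for (int c = 0; c < p; ++c) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int q = -r; q <= r; ++q) {
        int s = i + q;
        if (s < 0) s = 0;
        if (s >= n) s = n - 1;
        acc += m(s, c) * kernel[q + r];
      }
      out(i, c) = acc;
    }
  }
  return out;
}
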