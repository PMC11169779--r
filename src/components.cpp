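#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3-D connected-component labelling by breadth-first flood fill.
// mask: integer vector of length nx*ny*nz (column-major), nonzero = foreground.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// Returns integer labels (0 = background), components numbered 1.. in the
// order their first voxel appears in column-major scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);

  std::vector<int> di, dj, dk;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        di.push_back(dx); dj.push_back(dy); dk.push_back(dz);
      }
  const int noff = (int)di.size();

  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int o = 0; o < noff; ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] != 0 && lab[w] == 0) {
          lab[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// For each row of `a` (n x 3), the minimum Euclidean distance to any row
// of `b` (m x 3). Brute force; intended for surface point sets.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix a, NumericMatrix b) {
  const int n = a.nrow(), m = b.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// K-nearest-neighbour majority vote. query: n x 3, ref: m x 3, ref_lab:
// 0-based class per reference point, k neighbours. Tied votes go to the
// lowest class index. Returns 0-based class per query point.
// [[Rcpp::export]]
IntegerVector cpp_knn_vote(NumericMatrix query, NumericMatrix ref,
                           IntegerVector ref_lab, int k, int n_classes) {
  const int n = query.nrow(), m = ref.nrow();
  if (k > m) stop("k exceeds number of reference points");
  IntegerVector out(n);
  std::vector<std::pair<double, int> > d(m);
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    std::vector<int> votes(n_classes, 0);
    for (int j = 0; j < k; ++j) votes[ref_lab[d[j].second]]++;
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (votes[c] > votes[best]) best = c;  // ties keep lowest index
    out[i] = best;
  }
  return out;
}

// 3x3x3 box median filter with edge replication; standard edge-preserving
// denoiser for piecewise-constant volumes.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector arr, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> buf(27);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int m = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              int ii = std::min(std::max(i + di, 0), nx - 1);
              int jj = std::min(std::max(j + dj, 0), ny - 1);
              int kk = std::min(std::max(k + dk, 0), nz - 1);
              buf[m++] = arr[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
            }
        std::nth_element(buf.begin(), buf.begin() + 13, buf.begin() + 27);
        out[i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * k)] = buf[13];
      }
  return out;
}
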