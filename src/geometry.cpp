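#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact nearest-neighbour kernels for 3D point sets. All matrices are n x 3,
// all returned indices are 1-based. Brute force is deliberate: clouds here are
// at most a few thousand points and exactness (including deterministic
// lowest-index tie-breaking) is part of the contract.

// Greedy maximin (iterative farthest point) sampling. Selection starts at
// `start` (1-based); each successive pick maximizes the minimum squared
// distance to the already-selected set, ties broken by lowest input index.
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix pts, int m, int start) {
  const int n = pts.nrow();
  if (m < 1 || m > n) stop("m must be between 1 and the number of points");
  if (start < 1 || start > n) stop("start index out of range");
  const double* X = &pts(0, 0);
  const double* Y = X + n;
  const double* Z = Y + n;
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start - 1;
  out[0] = cur + 1;
  mind[cur] = -1.0; // the seed point is never reselected either
  for (int s = 1; s < m; ++s) {
    const double cx = X[cur], cy = Y[cur], cz = Z[cur];
    double best = -1.0;
    int besti = -1;
    for (int i = 0; i < n; ++i) {
      const double dx = X[i] - cx, dy = Y[i] - cy, dz = Z[i] - cz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < mind[i]) mind[i] = d;
      // strict > keeps the lowest index on ties; selected points sit at -1
      if (mind[i] > best) {
        best = mind[i];
        besti = i;
      }
    }
    cur = besti;
    out[s] = cur + 1;
    mind[cur] = -1.0; // never reselect
  }
  return out;
}

// K nearest reference points for each query point, rows sorted by
// (distance, reference index); exact, stable tie-break by lowest index.
// [[Rcpp::export]]
IntegerMatrix knn_cpp(NumericMatrix query, NumericMatrix ref, int k) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (k < 1 || k > nr) stop("K must be between 1 and the reference size");
  const double* QX = &query(0, 0);
  const double* QY = QX + nq;
  const double* QZ = QY + nq;
  const double* RX = &ref(0, 0);
  const double* RY = RX + nr;
  const double* RZ = RY + nr;
  IntegerMatrix out(nq, k);
  std::vector<std::pair<double, int> > d(nr);
  for (int i = 0; i < nq; ++i) {
    const double qx = QX[i], qy = QY[i], qz = QZ[i];
    for (int j = 0; j < nr; ++j) {
      const double dx = RX[j] - qx, dy = RY[j] - qy, dz = RZ[j] - qz;
      d[j] = std::make_pair(dx * dx + dy * dy + dz * dz, j);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) out(i, j) = d[j].second + 1;
  }
  return out;
}

// Nearest y-point for every x-point: 1-based indices and squared distances.
// [[Rcpp::export]]
List nn1_cpp(NumericMatrix x, NumericMatrix y) {
  const int nx = x.nrow(), ny = y.nrow();
  if (ny < 1) stop("reference cloud is empty");
  const double* XX = &x(0, 0);
  const double* XY = XX + nx;
  const double* XZ = XY + nx;
  const double* YX = &y(0, 0);
  const double* YY = YX + ny;
  const double* YZ = YY + ny;
  IntegerVector idx(nx);
  NumericVector d2(nx);
  for (int i = 0; i < nx; ++i) {
    const double px = XX[i], py = XY[i], pz = XZ[i];
    double best = R_PosInf;
    int besti = 0;
    for (int j = 0; j < ny; ++j) {
      const double dx = YX[j] - px, dy = YY[j] - py, dz = YZ[j] - pz;
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) {
        best = d;
        besti = j;
      }
    }
    idx[i] = besti + 1;
    d2[i] = best;
  }
  return List::create(_["idx"] = idx, _["dist2"] = d2);
}
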