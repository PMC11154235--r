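#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Balanced k-d tree over voxel centroids (world mm). Build is O(N log N)
// (median split by nth_element, axis cycling with depth), each query is
// O(log N) expected. Ties in nearest distance are broken toward the smallest
// original (flattened, column-major) point index so that results are
// deterministic and reproducible against an exhaustive scan.

namespace {

struct KDTree {
  const double *x, *y, *z;
  std::vector<int> ord;

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  void build(int lo, int hi, int depth) {
    if (hi - lo <= 1) return;
    const int ax = depth % 3;
    const int mid = lo + (hi - lo) / 2;
    std::nth_element(ord.begin() + lo, ord.begin() + mid, ord.begin() + hi,
                     [&](int a, int b) {
                       const double ca = coord(a, ax), cb = coord(b, ax);
                       return ca < cb || (ca == cb && a < b);
                     });
    build(lo, mid, depth + 1);
    build(mid + 1, hi, depth + 1);
  }

  void query(int lo, int hi, int depth, double qx, double qy, double qz,
             double &bd, int &bi) const {
    if (hi <= lo) return;
    const int ax = depth % 3;
    const int mid = lo + (hi - lo) / 2;
    const int p = ord[mid];
    const double dx = qx - x[p], dy = qy - y[p], dz = qz - z[p];
    const double d = (dx * dx + dy * dy) + dz * dz;
    if (d < bd || (d == bd && p < bi)) { bd = d; bi = p; }
    const double qc = ax == 0 ? qx : (ax == 1 ? qy : qz);
    const double diff = qc - coord(p, ax);
    if (diff < 0) {
      query(lo, mid, depth + 1, qx, qy, qz, bd, bi);
      if (diff * diff <= bd) query(mid + 1, hi, depth + 1, qx, qy, qz, bd, bi);
    } else {
      query(mid + 1, hi, depth + 1, qx, qy, qz, bd, bi);
      if (diff * diff <= bd) query(lo, mid, depth + 1, qx, qy, qz, bd, bi);
    }
  }
};

} // namespace

// pts: N x 3 source centroids (rows in flattened voxel order);
// queries: M x 3 template centroids. Returns 1-based nearest indices and
// Euclidean distances in mm.
// [[Rcpp::export]]
List cpp_nn_search(NumericMatrix pts, NumericMatrix queries) {
  const int n = pts.nrow();
  const R_xlen_t m = queries.nrow();
  if (n < 1) stop("empty point set");
  std::vector<double> X(n), Y(n), Z(n);
  for (int i = 0; i < n; i++) { X[i] = pts(i, 0); Y[i] = pts(i, 1); Z[i] = pts(i, 2); }
  KDTree kd;
  kd.x = X.data(); kd.y = Y.data(); kd.z = Z.data();
  kd.ord.resize(n);
  for (int i = 0; i < n; i++) kd.ord[i] = i;
  kd.build(0, n, 0);

  IntegerVector idx(m);
  NumericVector dist(m);
  for (R_xlen_t q = 0; q < m; q++) {
    double bd = std::numeric_limits<double>::infinity();
    int bi = n;
    kd.query(0, n, 0, queries(q, 0), queries(q, 1), queries(q, 2), bd, bi);
    idx[q] = bi + 1;
    dist[q] = std::sqrt(bd);
    if ((q & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
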