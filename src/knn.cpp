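#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fixed-radius k-nearest-neighbour search on a uniform bucket grid.
// Buckets have side length r, so all neighbours within r of a query point
// lie in the 3x3x3 block of buckets around it.  Ties at the k-th distance
// are broken by data row index so results are deterministic.

static inline long long bucket_key(double v, double r) {
  return (long long)std::floor(v / r);
}

// [[Rcpp::export]]
List radius_knn_cpp(NumericMatrix data, NumericMatrix query, double r, int k,
                    bool exclude_self) {
  const int n = data.nrow(), m = query.nrow();
  const double r2 = r * r;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(2 * (size_t)n + 16);
  const long long OFF = 1LL << 20;
  for (int j = 0; j < n; ++j) {
    long long cx = bucket_key(data(j, 0), r) + OFF;
    long long cy = bucket_key(data(j, 1), r) + OFF;
    long long cz = bucket_key(data(j, 2), r) + OFF;
    grid[cx + (cy << 21) + (cz << 42)].push_back(j);
  }
  IntegerMatrix idx(m, k);
  NumericMatrix dst(m, k);
  std::fill(idx.begin(), idx.end(), 0);       // 0 = no neighbour
  std::fill(dst.begin(), dst.end(), NA_REAL);
  std::vector<std::pair<double, int> > cand;
  for (int i = 0; i < m; ++i) {
    cand.clear();
    long long cx = bucket_key(query(i, 0), r) + OFF;
    long long cy = bucket_key(query(i, 1), r) + OFF;
    long long cz = bucket_key(query(i, 2), r) + OFF;
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
            grid.find((cx + dx) + ((cy + dy) << 21) + ((cz + dz) << 42));
          if (it == grid.end()) continue;
          const std::vector<int>& pts = it->second;
          for (size_t t = 0; t < pts.size(); ++t) {
            int j = pts[t];
            if (exclude_self && j == i) continue;
            double ddx = data(j, 0) - query(i, 0);
            double ddy = data(j, 1) - query(i, 1);
            double ddz = data(j, 2) - query(i, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= r2) cand.push_back(std::make_pair(d2, j));
          }
        }
    int take = std::min((int)cand.size(), k);
    if (take > 0) {
      std::partial_sort(cand.begin(), cand.begin() + take, cand.end());
      for (int t = 0; t < take; ++t) {
        idx(i, t) = cand[t].second + 1;       // 1-based for R
        dst(i, t) = std::sqrt(cand[t].first);
      }
    }
  }
  return List::create(Named("idx") = idx, Named("dist") = dst);
}
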