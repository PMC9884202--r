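// Grid-accelerated DBSCAN (Euclidean, 2D) and the 50-nm exclusion merge.
// Both bucket points into cells of side eps/radius so a region query only
// scans the 3x3 cell neighbourhood.
#include <Rcpp.h>
#include <cmath>
#include <deque>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

typedef long long CellKey;

inline CellKey cell_key(double v, double w, double cell) {
  // 2^21 cells per axis is ample for nm-scale fields
  long long cx = (long long)std::floor(v / cell);
  long long cy = (long long)std::floor(w / cell);
  return (cx << 21) ^ (cy & ((1LL << 21) - 1));
}

struct Grid {
  std::unordered_map<CellKey, std::vector<int> > cells;
  double cell;
  const double *x;
  const double *y;

  Grid(const double *x_, const double *y_, int n, double cell_)
      : cell(cell_), x(x_), y(y_) {
    cells.reserve(n);
    for (int i = 0; i < n; ++i)
      cells[cell_key(x[i], y[i], cell)].push_back(i);
  }

  // indices within `radius` of point (qx, qy); includes the point itself
  void query(double qx, double qy, double radius, std::vector<int> &out) const {
    out.clear();
    const double r2 = radius * radius;
    long long cx = (long long)std::floor(qx / cell);
    long long cy = (long long)std::floor(qy / cell);
    for (long long ix = cx - 1; ix <= cx + 1; ++ix) {
      for (long long iy = cy - 1; iy <= cy + 1; ++iy) {
        CellKey key = (ix << 21) ^ (iy & ((1LL << 21) - 1));
        std::unordered_map<CellKey, std::vector<int> >::const_iterator it =
            cells.find(key);
        if (it == cells.end()) continue;
        for (size_t t = 0; t < it->second.size(); ++t) {
          int j = it->second[t];
          const double dx = x[j] - qx;
          const double dy = y[j] - qy;
          if (dx * dx + dy * dy <= r2) out.push_back(j);
        }
      }
    }
  }
};

} // namespace

// Cluster labels: 0 for DBSCAN noise, 1..K for clusters. A point is core if
// its closed eps-neighbourhood (self included) holds >= min_pts points.
// Clusters are numbered in order of the first core point encountered when
// scanning points in index order, which makes labels deterministic.
// [[Rcpp::export]]
IntegerVector dbscan_cpp(NumericVector x, NumericVector y, double eps,
                         int min_pts) {
  const int n = x.size();
  IntegerVector labels(n, 0);
  if (n == 0) return labels;
  std::vector<int> state(n, 0); // 0 unvisited, 1 visited
  Grid grid(REAL(x), REAL(y), n, eps);
  std::vector<int> neigh, neigh2;
  int cluster = 0;
  for (int i = 0; i < n; ++i) {
    if (state[i]) continue;
    state[i] = 1;
    grid.query(x[i], y[i], eps, neigh);
    if ((int)neigh.size() < min_pts) continue; // noise unless claimed later
    ++cluster;
    labels[i] = cluster;
    std::deque<int> seeds(neigh.begin(), neigh.end());
    while (!seeds.empty()) {
      int j = seeds.front();
      seeds.pop_front();
      if (labels[j] == 0) labels[j] = cluster; // border or unprocessed
      if (state[j]) continue;
      state[j] = 1;
      grid.query(x[j], y[j], eps, neigh2);
      if ((int)neigh2.size() >= min_pts)
        for (size_t t = 0; t < neigh2.size(); ++t) seeds.push_back(neigh2[t]);
    }
  }
  return labels;
}

// Keep flag per noise point: FALSE when the nearest object point is closer
// than `radius` (strictly), per the exclusion rule used when merging
// simulated structure and noise localizations.
// [[Rcpp::export]]
LogicalVector exclusion_keep_cpp(NumericVector nx, NumericVector ny,
                                 NumericVector ox, NumericVector oy,
                                 double radius) {
  const int n = nx.size();
  LogicalVector keep(n, true);
  if (ox.size() == 0 || radius <= 0) return keep;
  Grid grid(REAL(ox), REAL(oy), ox.size(), radius);
  std::vector<int> hits;
  const double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    grid.query(nx[i], ny[i], radius, hits);
    for (size_t t = 0; t < hits.size(); ++t) {
      const double dx = ox[hits[t]] - nx[i];
      const double dy = oy[hits[t]] - ny[i];
      if (dx * dx + dy * dy < r2) {
        keep[i] = false;
        break;
      }
    }
  }
  return keep;
}
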