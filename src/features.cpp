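// Batched per-localization feature extraction: sorted kNN distances and the
// smoothed, max-aligned neighbour-direction histogram. Neighbour search uses
// an x-sorted sweep with a bounded max-heap: candidates are visited outward
// from the query in x until the x-gap alone exceeds the current kth
// distance, which prunes most of the subset in dense regions.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Neigh {
  double d2;
  int idx;
};

inline bool neigh_less(const Neigh &a, const Neigh &b) {
  // ties in distance broken by original point index for determinism
  if (a.d2 != b.d2) return a.d2 < b.d2;
  return a.idx < b.idx;
}

// bin index in [0, nb) for an angle in [-pi, pi); pi wraps to -pi
inline int angle_bin(double theta, int nb) {
  const double pi = M_PI;
  if (theta >= pi) theta -= 2.0 * pi;
  int b = (int)std::floor((theta + pi) / (2.0 * pi / nb));
  if (b < 0) b = 0;
  if (b >= nb) b = nb - 1;
  return b;
}

// x-sorted point index for repeated kNN queries over one subset
struct KnnSweep {
  const double *x, *y;
  int n;
  std::vector<int> ord;    // original indices sorted by (x, idx)
  std::vector<int> pos;    // position of each original index in ord
  std::vector<Neigh> heap; // scratch max-heap of current best k

  KnnSweep(const double *x_, const double *y_, int n_) : x(x_), y(y_), n(n_) {
    ord.resize(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (x[a] != x[b]) return x[a] < x[b];
      return a < b;
    });
    pos.resize(n);
    for (int p = 0; p < n; ++p) pos[ord[p]] = p;
  }

  void consider(int oj, double xi, double yi, int k) {
    const double dx = x[oj] - xi;
    const double dy = y[oj] - yi;
    Neigh cand;
    cand.d2 = dx * dx + dy * dy;
    cand.idx = oj;
    if ((int)heap.size() < k) {
      heap.push_back(cand);
      std::push_heap(heap.begin(), heap.end(), neigh_less);
    } else if (neigh_less(cand, heap.front())) {
      std::pop_heap(heap.begin(), heap.end(), neigh_less);
      heap.back() = cand;
      std::push_heap(heap.begin(), heap.end(), neigh_less);
    }
  }

  // k nearest neighbours of original index i, sorted by (d2, idx)
  void query(int i, int k, std::vector<Neigh> &out) {
    heap.clear();
    const double xi = x[i], yi = y[i];
    int left = pos[i] - 1, right = pos[i] + 1;
    bool left_open = left >= 0, right_open = right < n;
    while (left_open || right_open) {
      const bool full = (int)heap.size() == k;
      const double bound = full ? heap.front().d2 : HUGE_VAL;
      if (left_open) {
        const double dx = xi - x[ord[left]];
        if (full && dx * dx > bound) left_open = false;
      }
      if (right_open) {
        const double dx = x[ord[right]] - xi;
        if (full && dx * dx > bound) right_open = false;
      }
      if (!left_open && !right_open) break;
      // visit the side with the smaller x-gap first
      bool go_left;
      if (!left_open) {
        go_left = false;
      } else if (!right_open) {
        go_left = true;
      } else {
        go_left = (xi - x[ord[left]]) <= (x[ord[right]] - xi);
      }
      if (go_left) {
        consider(ord[left], xi, yi, k);
        if (--left < 0) left_open = false;
      } else {
        consider(ord[right], xi, yi, k);
        if (++right >= n) right_open = false;
      }
    }
    out.assign(heap.begin(), heap.end());
    std::sort(out.begin(), out.end(), neigh_less);
  }
};

// shared histogram post-processing in plain C++ (no R allocations in the
// hot loop)
void align_histogram(const std::vector<double> &counts, int smooth_width,
                     double align, bool normalize, std::vector<double> &out) {
  const int nb = (int)counts.size();
  const int half = smooth_width / 2;
  std::vector<double> sm(nb);
  for (int b = 0; b < nb; ++b) {
    double s = 0.0;
    for (int t = -half; t <= half; ++t) {
      int bb = ((b + t) % nb + nb) % nb;
      s += counts[bb];
    }
    sm[b] = s / smooth_width;
  }
  int max_bin = 0;
  for (int b = 1; b < nb; ++b)
    if (sm[b] > sm[max_bin]) max_bin = b;
  const double delta = 2.0 * M_PI / nb;
  int target = 0;
  double best = HUGE_VAL;
  for (int b = 0; b < nb; ++b) {
    double centre = -M_PI + (b + 0.5) * delta;
    double diff = std::fabs(centre - align);
    if (diff < best) {
      best = diff;
      target = b;
    }
  }
  out.assign(nb, 0.0);
  for (int b = 0; b < nb; ++b) {
    int bb = ((b - max_bin + target) % nb + nb) % nb;
    out[bb] = sm[b];
  }
  if (normalize) {
    double s = 0.0;
    for (int b = 0; b < nb; ++b) s += out[b];
    if (s > 0)
      for (int b = 0; b < nb; ++b) out[b] /= s;
  }
}

} // namespace

// Histogram post-processing shared with the R reference path: circular boxcar
// smoothing, circular shift of the global-maximum bin onto the bin whose
// centre is closest to `align`, optional normalization to sum 1.
// [[Rcpp::export]]
NumericVector align_histogram_cpp(NumericVector counts, int smooth_width,
                                  double align, bool normalize) {
  std::vector<double> in(counts.begin(), counts.end()), out;
  align_histogram(in, smooth_width, align, normalize, out);
  return NumericVector(out.begin(), out.end());
}

// Feature block for every point of one subset.
// Returns a transposed (k + n_bins) x n matrix (one contiguous column per
// point: k sorted NN distances then the aligned direction histogram); the
// R wrapper transposes back.
// [[Rcpp::export]]
NumericMatrix feature_block_cpp(NumericVector x, NumericVector y, int k,
                                int n_bins, int smooth_width, double align,
                                bool normalize) {
  const int n = x.size();
  if (n < k + 1) stop("subset of size %d cannot supply %d neighbours", n, k);
  const int nf = k + n_bins;
  NumericMatrix out(nf, n);
  KnnSweep sweep(REAL(x), REAL(y), n);
  std::vector<Neigh> sel;
  std::vector<double> counts(n_bins), hist;
  sel.reserve(k);
  for (int i = 0; i < n; ++i) {
    sweep.query(i, k, sel);
    double *col = &out(0, i);
    std::fill(counts.begin(), counts.end(), 0.0);
    const double xi = x[i], yi = y[i];
    for (int r = 0; r < k; ++r) {
      col[r] = std::sqrt(sel[r].d2);
      const int j = sel[r].idx;
      const double theta = std::atan2(y[j] - yi, x[j] - xi);
      counts[angle_bin(theta, n_bins)] += 1.0;
    }
    align_histogram(counts, smooth_width, align, normalize, hist);
    for (int b = 0; b < n_bins; ++b) col[k + b] = hist[b];
  }
  return out;
}

// Mean distance to the first m nearest neighbours for every point
// (used by the nearest-neighbour outlier filter when feature columns are
// not available).
// [[Rcpp::export]]
NumericVector knn_mean_dist_cpp(NumericVector x, NumericVector y, int m) {
  const int n = x.size();
  if (n < m + 1) stop("need at least m + 1 points");
  NumericVector out(n);
  KnnSweep sweep(REAL(x), REAL(y), n);
  std::vector<Neigh> sel;
  sel.reserve(m);
  for (int i = 0; i < n; ++i) {
    sweep.query(i, m, sel);
    double s = 0.0;
    for (int r = 0; r < m; ++r) s += std::sqrt(sel[r].d2);
    out[i] = s / m;
  }
  return out;
}
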