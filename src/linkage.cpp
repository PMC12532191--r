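#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Single-linkage connected components on 2D points with an optional temporal
// gate: points i, j are linked when dist(i, j) <= radius and (if max_gap >= 0)
// |frame_i - frame_j| <= max_gap. Uses a uniform grid of cell size `radius`
// so only the 3x3 neighbourhood needs checking, plus union-find.
// Returns 1-based component labels.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a); b = uf_find(parent, b);
  if (a != b) parent[b] = a;
}

// [[Rcpp::export]]
IntegerVector spatial_linkage(NumericVector x, NumericVector y,
                              double radius,
                              Nullable<IntegerVector> frame = R_NilValue,
                              double max_gap = -1) {
  const int n = x.size();
  IntegerVector labels(n);
  if (n == 0) return labels;
  if (radius <= 0) stop("linkage radius must be > 0");

  const bool temporal = frame.isNotNull() && max_gap >= 0;
  IntegerVector fr = temporal ? IntegerVector(frame.get()) : IntegerVector(0);

  // grid bucketing
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  auto key = [&](long long cx, long long cy) { return cx * 2000003LL + cy; };
  std::vector<long long> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (long long) std::floor(x[i] / radius);
    cy[i] = (long long) std::floor(y[i] / radius);
    grid[key(cx[i], cy[i])].push_back(i);
  }

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  const double r2 = radius * radius;

  for (int i = 0; i < n; ++i) {
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(key(cx[i] + dx, cy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy > r2) continue;
          if (temporal && std::abs((double) fr[i] - fr[j]) > max_gap) continue;
          uf_union(parent, i, j);
        }
      }
    }
  }

  // relabel components 1..k in order of first appearance
  std::unordered_map<int, int> remap;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int root = uf_find(parent, i);
    auto it = remap.find(root);
    if (it == remap.end()) { remap[root] = ++next; labels[i] = next; }
    else labels[i] = it->second;
  }
  return labels;
}

// Histogram of unordered pair distances for pair-correlation estimation.
// Counts pairs with distance in [k * bin_width, (k+1) * bin_width), k < n_bins.
// Pairs at distance 0 fall in the first bin; distances >= r_max are dropped.
// [[Rcpp::export]]
NumericVector pair_distance_hist(NumericVector x, NumericVector y,
                                 double bin_width, int n_bins) {
  const int n = x.size();
  NumericVector h(n_bins);
  const double r_max = bin_width * n_bins;
  const double r2max = r_max * r_max;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j], dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 >= r2max) continue;
      int k = (int) (std::sqrt(d2) / bin_width);
      if (k >= n_bins) k = n_bins - 1;  // numeric guard
      h[k] += 1.0;
    }
  }
  return h;
}
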