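#include <Rcpp.h>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Count (x, y) pairs with Euclidean distance <= r for each radius.
// radii must be sorted increasing; returns cumulative counts per radius.
// [[Rcpp::export(name = ".pair_count_within")]]
IntegerVector pair_count_within(NumericVector xx, NumericVector xy,
                                NumericVector yx, NumericVector yy,
                                NumericVector radii) {
  const int nx = xx.size(), ny = yx.size(), nr = radii.size();
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  std::vector<long long> counts(nr, 0);
  const double rmax2 = r2[nr - 1];
  for (int i = 0; i < nx; ++i) {
    const double xi = xx[i], yi = xy[i];
    for (int j = 0; j < ny; ++j) {
      const double dx = yx[j] - xi, dy = yy[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) continue;
      // first radius with r^2 >= d2
      int k = int(std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin());
      if (k < nr) ++counts[k];
    }
  }
  IntegerVector out(nr);
  long long acc = 0;
  for (int k = 0; k < nr; ++k) { acc += counts[k]; out[k] = (int)acc; }
  return out;
}

// 8-connected labelling of a binary matrix (two-pass union-find).
// [[Rcpp::export(name = ".label_components8")]]
IntegerMatrix label_components8(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int best = 0;
      // previously-visited 8-neighbours (scan order: columns, rows within)
      const int di[4] = {-1, -1,  0, 1};
      const int dj[4] = { 0, -1, -1, -1};
      for (int q = 0; q < 4; ++q) {
        int ii = i + di[q], jj = j + dj[q];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        int l = lab(ii, jj);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) { best = ++next; parent.push_back(best); }
      lab(i, j) = best;
    }
  }
  // relabel to 1..n consecutive
  std::vector<int> remap(next + 1, 0);
  int n = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++n;
        lab(i, j) = remap[r];
      }
  return lab;
}
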