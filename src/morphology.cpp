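#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first search.
// connectivity: 4 or 8. Labels are 1..K in scan order of first-encountered
// pixel; background is 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  int ndir = (connectivity == 8) ? 8 : 4;
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int d = 0; d < ndir; ++d) {
          int ni = ci + dr[d], nj = cj + dc[d];
          if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            stack.push_back(ni + nj * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Binary dilation with a disk structuring element of the given radius
// (Euclidean, pixels at distance <= radius from any true pixel become true).
// [[Rcpp::export(name = ".binary_dilate")]]
LogicalMatrix binary_dilate(LogicalMatrix mask, int radius) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix out(nr, nc);
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(mask);
  int r2 = radius * radius;
  // precompute disk offsets
  std::vector<int> offr, offc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= r2) { offr.push_back(a); offc.push_back(b); }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      for (size_t k = 0; k < offr.size(); ++k) {
        int ni = i + offr[k], nj = j + offc[k];
        if (ni >= 0 && ni < nr && nj >= 0 && nj < nc) out(ni, nj) = true;
      }
    }
  }
  return out;
}
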