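#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Zhang-Suen topology-preserving thinning of a binary mask (rows x cols,
// nonzero = foreground). Returns a mask of the same shape whose foreground
// is the 1-pixel-wide, 8-connected skeleton.
// [[Rcpp::export(name = ".cpp_thin")]]
IntegerMatrix cpp_thin(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> img(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[i + j * nr] = mask(i, j) != 0 ? 1 : 0;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[i + j * nr];
  };

  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!img[i + j * nr]) continue;
          // neighbours P2..P9 clockwise from north (row - 1)
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int P[8] = {p2, p3, p4, p5, p6, p7, p8, p9};
          int A = 0;
          for (int t = 0; t < 8; ++t)
            if (P[t] == 0 && P[(t + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(i + j * nr);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t t = 0; t < kill.size(); ++t) img[kill[t]] = 0;
    }
  }

  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[i + j * nr];
  return out;
}

// 8-connected component labelling of a binary mask; background = 0,
// components numbered 1..n in scan order.
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back({i, j});
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back({ni, nj});
            }
          }
        }
      }
    }
  }
  return lab;
}
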