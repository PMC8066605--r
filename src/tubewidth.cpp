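#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Neighbour labelling used throughout: P2..P9 clockwise from North,
//   P9 P2 P3
//   P8 P1 P4
//   P7 P6 P5
// (row index grows downward, column index grows rightward).

static inline int px(const std::vector<int>& v, int nr, int nc, int r, int c) {
  if (r < 0 || r >= nr || c < 0 || c >= nc) return 0;
  return v[(size_t)c * nr + r];
}

// [[Rcpp::export]]
IntegerMatrix cpp_zhang_suen(IntegerMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> a(img.begin(), img.end());
  std::vector<size_t> kill;
  kill.reserve(1024);
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      kill.clear();
      for (int c = 0; c < nc; ++c) {
        for (int r = 0; r < nr; ++r) {
          if (!a[(size_t)c * nr + r]) continue;
          int p2 = px(a, nr, nc, r - 1, c);
          int p3 = px(a, nr, nc, r - 1, c + 1);
          int p4 = px(a, nr, nc, r,     c + 1);
          int p5 = px(a, nr, nc, r + 1, c + 1);
          int p6 = px(a, nr, nc, r + 1, c);
          int p7 = px(a, nr, nc, r + 1, c - 1);
          int p8 = px(a, nr, nc, r,     c - 1);
          int p9 = px(a, nr, nc, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          int A = 0;
          for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0) continue;
            if (p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0) continue;
            if (p2 * p6 * p8 != 0) continue;
          }
          kill.push_back((size_t)c * nr + r);
        }
      }
      if (!kill.empty()) {
        changed = true;
        for (size_t i = 0; i < kill.size(); ++i) a[kill[i]] = 0;
      }
    }
  }
  IntegerMatrix out(nr, nc);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

// 8-connected component labelling; labels assigned in column-major seed
// order (the R storage order), breadth-first from each seed.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (!dr && !dc) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              q.push(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}
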