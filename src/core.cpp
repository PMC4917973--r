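#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Arrival-time propagation for augmented fast marching skeletonization.
// Boundary pixels carry T = 0 and a boundary parameter U; interior
// foreground pixels receive T by a first-order upwind eikonal solve over
// 4-neighbours and inherit U from the neighbour that last improved their
// arrival time (the upwind source). Heap ties resolved by insertion order.

namespace {

struct HeapNode {
  double t;
  long long seq;
  int idx;
};

struct HeapCmp {
  bool operator()(const HeapNode& a, const HeapNode& b) const {
    if (a.t != b.t) return a.t > b.t;
    return a.seq > b.seq;  // earlier insertion pops first
  }
};

}  // namespace

// Each boundary pixel is its own source; the marching front carries the
// source along, and a pixel's arrival time is the exact Euclidean distance
// to its inherited source. This keeps U consistent with the nearest
// boundary point (up to the classic 4-neighbour propagation error of well
// under a pixel) while preserving the fast-marching visit order.
// [[Rcpp::export(name = ".fmmPropagate")]]
List fmm_propagate(IntegerMatrix mask, NumericMatrix U0, IntegerMatrix boundary) {
  const int nr = mask.nrow(), nc = mask.ncol(), n = nr * nc;
  NumericMatrix T(nr, nc), U(nr, nc);
  std::vector<int> src(n, -1);
  std::vector<char> frozen(n, 0);
  std::fill(T.begin(), T.end(), R_PosInf);
  std::fill(U.begin(), U.end(), NA_REAL);

  std::priority_queue<HeapNode, std::vector<HeapNode>, HeapCmp> heap;
  long long seq = 0;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (boundary(i, j)) {
        int idx = j * nr + i;
        T(i, j) = 0.0;
        U(i, j) = U0(i, j);
        src[idx] = idx;
        heap.push({0.0, seq++, idx});
      }

  while (!heap.empty()) {
    HeapNode top = heap.top();
    heap.pop();
    int i = top.idx % nr, j = top.idx / nr;
    if (frozen[top.idx]) continue;
    if (top.t != T(i, j)) continue;  // superseded entry
    frozen[top.idx] = 1;
    int s = src[top.idx];
    int si = s % nr, sj = s / nr;
    for (int k = 0; k < 4; ++k) {
      int ri = i + dr[k], cj = j + dc[k];
      if (ri < 0 || ri >= nr || cj < 0 || cj >= nc) continue;
      if (!mask(ri, cj)) continue;
      int nidx = cj * nr + ri;
      if (frozen[nidx]) continue;
      double ddi = ri - si, ddj = cj - sj;
      double tn = std::sqrt(ddi * ddi + ddj * ddj);
      if (tn < T(ri, cj)) {
        T(ri, cj) = tn;
        U(ri, cj) = U(si, sj);
        src[nidx] = s;
        heap.push({tn, seq++, nidx});
      }
    }
  }

  return List::create(_["U"] = U, _["T"] = T);
}

// Guo-Hall two-subiteration thinning of a binary raster to unit width.
// Handles 2-px diagonal ridges (which Zhang-Suen-style schemes either keep
// or erase entirely) while preserving connectivity and line ends.
// [[Rcpp::export(name = ".thinMask")]]
IntegerMatrix thin_mask(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix m = clone(mask);
  std::vector<int> kill;
  bool changed = true;

  auto at = [&](int i, int j) -> int {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return m(i, j);
  };

  while (changed) {
    changed = false;
    for (int iter = 0; iter < 2; ++iter) {
      kill.clear();
      for (int j = 0; j < nc; ++j)
        for (int i = 0; i < nr; ++i) {
          if (!m(i, j)) continue;
          int p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
              p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
              p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int mcond = (iter == 0) ? ((p6 | p7 | (!p9)) & p8)
                                  : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && mcond == 0)
            kill.push_back(j * nr + i);
        }
      if (!kill.empty()) {
        changed = true;
        for (int idx : kill) m[idx] = 0;
      }
    }
  }
  return m;
}

// k-th smallest (1-based) of each row of X; lower-median order statistic
// when k = floor((n + 1) / 2).
// [[Rcpp::export(name = ".rowKthSmallest")]]
NumericVector row_kth_smallest(NumericMatrix X, int k) {
  const int nr = X.nrow(), nc = X.ncol();
  if (k < 1 || k > nc) stop("order statistic out of range");
  NumericVector out(nr);
  std::vector<double> buf(nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) buf[j] = X(i, j);
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    out[i] = buf[k - 1];
  }
  return out;
}
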