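#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Index mapping for out-of-bounds access. reflect: -1 -> 0, -2 -> 1 (edge
// included, scipy "reflect"); replicate: clamp to the nearest edge pixel.
static inline int pad_idx(int i, int n, bool reflect) {
  if (n == 1) return 0;
  if (reflect) {
    // period 2n: fold until in range
    while (i < 0 || i >= n) {
      if (i < 0) i = -i - 1;
      if (i >= n) i = 2 * n - i - 1;
    }
    return i;
  }
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// [[Rcpp::export(name = ".cpp_median_filter")]]
NumericMatrix cpp_median_filter(const NumericMatrix& x, int mh, int nh,
                                bool reflect) {
  const int M = x.nrow(), N = x.ncol();
  const int rh = mh / 2, rw = nh / 2;
  NumericMatrix out(M, N);
  std::vector<double> buf(mh * nh);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      int p = 0;
      for (int dj = -rw; dj <= rw; ++dj) {
        const int jj = pad_idx(n + dj, N, reflect);
        for (int di = -rh; di <= rh; ++di) {
          const int ii = pad_idx(m + di, M, reflect);
          buf[p++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + p / 2, buf.begin() + p);
      out(m, n) = buf[p / 2];
    }
  }
  return out;
}

// Binary erosion: pixel kept iff every structuring-element neighbour is in
// the mask; positions outside the image count as background, so objects
// touching the border are eroded there.
// [[Rcpp::export(name = ".cpp_erode")]]
LogicalMatrix cpp_erode(const LogicalMatrix& mask, const LogicalMatrix& se) {
  const int M = mask.nrow(), N = mask.ncol();
  const int rh = se.nrow() / 2, rw = se.ncol() / 2;
  LogicalMatrix out(M, N);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      bool keep = true;
      for (int dj = -rw; dj <= rw && keep; ++dj) {
        for (int di = -rh; di <= rh && keep; ++di) {
          if (!se(di + rh, dj + rw)) continue;
          const int ii = m + di, jj = n + dj;
          if (ii < 0 || ii >= M || jj < 0 || jj >= N || !mask(ii, jj))
            keep = false;
        }
      }
      out(m, n) = keep;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_dilate")]]
LogicalMatrix cpp_dilate(const LogicalMatrix& mask, const LogicalMatrix& se) {
  const int M = mask.nrow(), N = mask.ncol();
  const int rh = se.nrow() / 2, rw = se.ncol() / 2;
  LogicalMatrix out(M, N);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      bool hit = false;
      for (int dj = -rw; dj <= rw && !hit; ++dj) {
        for (int di = -rh; di <= rh && !hit; ++di) {
          if (!se(di + rh, dj + rw)) continue;
          const int ii = m + di, jj = n + dj;
          if (ii >= 0 && ii < M && jj >= 0 && jj < N && mask(ii, jj))
            hit = true;
        }
      }
      out(m, n) = hit;
    }
  }
  return out;
}

// Mean of `guide` over the SE neighbourhood intersected with `mask`
// (complement = true intersects with !mask). NA where the intersection is
// empty; out-of-image positions never contribute.
// [[Rcpp::export(name = ".cpp_local_mean")]]
NumericMatrix cpp_local_mean(const NumericMatrix& guide,
                             const LogicalMatrix& mask,
                             const LogicalMatrix& se, bool complement) {
  const int M = guide.nrow(), N = guide.ncol();
  const int rh = se.nrow() / 2, rw = se.ncol() / 2;
  NumericMatrix out(M, N);
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      double s = 0.0;
      int cnt = 0;
      for (int dj = -rw; dj <= rw; ++dj) {
        for (int di = -rh; di <= rh; ++di) {
          if (!se(di + rh, dj + rw)) continue;
          const int ii = m + di, jj = n + dj;
          if (ii < 0 || ii >= M || jj < 0 || jj >= N) continue;
          const bool inside = mask(ii, jj);
          if (inside != complement) {
            s += guide(ii, jj);
            ++cnt;
          }
        }
      }
      out(m, n) = cnt > 0 ? s / cnt : NA_REAL;
    }
  }
  return out;
}

// 4-connected component labelling of a binary mask; labels 1..n_comp in
// first-encounter (column-major) order, 0 for background.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  const int M = mask.nrow(), N = mask.ncol();
  IntegerMatrix lab(M, N);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  for (int n = 0; n < N; ++n) {
    for (int m = 0; m < M; ++m) {
      if (!mask(m, n) || lab(m, n) != 0) continue;
      lab(m, n) = ++next;
      q.push(std::make_pair(m, n));
      while (!q.empty()) {
        const int cm = q.front().first, cn = q.front().second;
        q.pop();
        for (int d = 0; d < 4; ++d) {
          const int ii = cm + di[d], jj = cn + dj[d];
          if (ii < 0 || ii >= M || jj < 0 || jj >= N) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}
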