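#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Reflective index (scipy-style "reflect": d c b a | a b c d), valid for any
// finite offset as long as n >= 1.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// ---------------------------------------------------------------------------
// Grayscale erosion / dilation with an arbitrary (possibly non-flat)
// structuring element given as offset lists plus per-offset heights.
// Erosion:  E(x) = min_s f(x + s) - b(s)
// Dilation: D(x) = max_s f(x - s) + b(s)
// Boundaries are handled by reflective padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gray_erode(NumericMatrix img, IntegerVector dr,
                             IntegerVector dc, NumericVector height) {
  const int nr = img.nrow(), nc = img.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_PosInf;
      for (int s = 0; s < k; ++s) {
        const int rr = reflect_idx(r + dr[s], nr);
        const int cc = reflect_idx(c + dc[s], nc);
        const double v = img(rr, cc) - height[s];
        if (v < m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gray_dilate(NumericMatrix img, IntegerVector dr,
                              IntegerVector dc, NumericVector height) {
  const int nr = img.nrow(), nc = img.ncol(), k = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (int s = 0; s < k; ++s) {
        const int rr = reflect_idx(r - dr[s], nr);
        const int cc = reflect_idx(c - dc[s], nc);
        const double v = img(rr, cc) + height[s];
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Population variance in a (2r+1)x(2r+1) square window, reflective padding.
// Computed from running sums over a reflectively padded copy so the cost is
// O(n) per pixel in the window radius, not the window area.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_box_variance(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int w = 2 * radius + 1;
  const double n = (double)w * (double)w;
  // padded sums along rows first
  NumericMatrix s1(nr, nc), s2(nr, nc);   // row-window partial sums
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double a = 0, b = 0;
      for (int d = -radius; d <= radius; ++d) {
        const double v = img(reflect_idx(r + d, nr), c);
        a += v; b += v * v;
      }
      s1(r, c) = a; s2(r, c) = b;
    }
  }
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double a = 0, b = 0;
      for (int d = -radius; d <= radius; ++d) {
        const int cc = reflect_idx(c + d, nc);
        a += s1(r, cc); b += s2(r, cc);
      }
      const double mu = a / n;
      double v = b / n - mu * mu;
      out(r, c) = (v > 0) ? v : 0.0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Median filter on an integer-valued matrix, square (2r+1)^2 window,
// reflective padding. Used to smooth EDF slice-index maps.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_median_filter_int(IntegerMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius < 1) return clone(img);
  const int w = 2 * radius + 1, n = w * w;
  IntegerMatrix out(nr, nc);
  std::vector<int> buf(n);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = 0;
      for (int dc = -radius; dc <= radius; ++dc) {
        const int cc = reflect_idx(c + dc, nc);
        for (int dr = -radius; dr <= radius; ++dr)
          buf[idx++] = img(reflect_idx(r + dr, nr), cc);
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(r, c) = buf[n / 2];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, kernel truncated at 4*sigma, reflective padding.
// sigma <= 0 returns a copy.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  const int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double ksum = 0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * (double)i * (double)i / (sigma * sigma));
    ksum += k[i + radius];
  }
  for (double &v : k) v /= ksum;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * img(reflect_idx(r + d, nr), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0;
      for (int d = -radius; d <= radius; ++d)
        acc += k[d + radius] * tmp(r, reflect_idx(c + d, nc));
      out(r, c) = acc;
    }
  return out;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a logical mask, 8-connectivity,
// consecutive positive labels in raster-scan discovery order.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.clear();
      stack.push_back(r + nr * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % nr, pc = p / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc) continue;
            const int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && !lab(rr, cc)) {
              lab(rr, cc) = next;
              stack.push_back(rr + nr * cc);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Seeded watershed (priority flood) of the inverted landscape of `height`:
// flooding starts at labelled seeds, highest `height` first, restricted to
// `mask`. Equal heights are resolved in insertion (FIFO) order so the result
// is deterministic.
// ---------------------------------------------------------------------------

struct WsNode {
  double h; long order; int idx, label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.h != b.h) return a.h < b.h;      // max-heap on height
    return a.order > b.order;              // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix cpp_seeded_watershed(NumericMatrix height, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  const int nr = height.nrow(), nc = height.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        lab(r, c) = seeds(r, c);
        pq.push({height(r, c), order++, r + nr * c, seeds(r, c)});
      }
  while (!pq.empty()) {
    const WsNode nd = pq.top(); pq.pop();
    const int pr = nd.idx % nr, pc = nd.idx / nr;
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (!dr && !dc) continue;
        const int rr = pr + dr, cc = pc + dc;
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (!mask(rr, cc) || lab(rr, cc)) continue;
        lab(rr, cc) = nd.label;
        pq.push({height(rr, cc), order++, rr + nr * cc, nd.label});
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Flat maximum filter over a disk of the given radius (used for regional
// maxima detection). Reflective padding.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_max_filter_disk(NumericMatrix img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dr, dc;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      if (a * a + b * b <= radius * radius) { dr.push_back(a); dc.push_back(b); }
  const int k = dr.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = R_NegInf;
      for (int s = 0; s < k; ++s) {
        const double v = img(reflect_idx(r + dr[s], nr), reflect_idx(c + dc[s], nc));
        if (v > m) m = v;
      }
      out(r, c) = m;
    }
  return out;
}
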