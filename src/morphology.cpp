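#include <Rcpp.h>
#include <vector>
#include <deque>
using namespace Rcpp;

// Connected-component labelling of a logical matrix (4- or 8-connectivity).
// Returns an integer matrix of labels (0 = background), labels are assigned
// in raster-scan order of first encounter.
// [[Rcpp::export(name = ".cpp_label")]]
IntegerMatrix cpp_label(const LogicalMatrix &mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::fill(lab.begin(), lab.end(), 0);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int ndir = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.clear();
      q.push_back(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop_front();
        for (int d = 0; d < ndir; ++d) {
          int rr = p.first + dr[d], cc = p.second + dc[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push_back(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

static void run_minmax_1d(const std::vector<double> &x, std::vector<double> &y,
                          int half, bool takeMax) {
  // brute-force windowed min/max; windows here are small (<= ~15 px)
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    double v = x[lo];
    for (int j = lo + 1; j <= hi; ++j)
      v = takeMax ? std::max(v, x[j]) : std::min(v, x[j]);
    y[i] = v;
  }
}

// Separable box (rectangular structuring element) grayscale erosion/dilation.
// half-widths hr (rows) and hc (cols); op = 0 erode (min), 1 dilate (max).
// [[Rcpp::export(name = ".cpp_box_minmax")]]
NumericMatrix cpp_box_minmax(const NumericMatrix &img, int hr, int hc, int op) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const bool takeMax = (op == 1);
  std::vector<double> buf, res;
  // columns pass
  NumericMatrix tmp(H, W);
  buf.resize(H);
  res.resize(H);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) buf[r] = img(r, c);
    run_minmax_1d(buf, res, hr, takeMax);
    for (int r = 0; r < H; ++r) tmp(r, c) = res[r];
  }
  // rows pass
  buf.resize(W);
  res.resize(W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) buf[c] = tmp(r, c);
    run_minmax_1d(buf, res, hc, takeMax);
    for (int c = 0; c < W; ++c) out(r, c) = res[c];
  }
  return out;
}
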