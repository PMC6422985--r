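#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Index helper for column-major 4D arrays (H, W, C, N).
static inline R_xlen_t idx4(int i, int j, int c, int n, int H, int W, int C) {
  return (R_xlen_t)i + (R_xlen_t)H * (j + (R_xlen_t)W * (c + (R_xlen_t)C * n));
}

static void dims4(const NumericVector& x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int k = 0; k < 4; ++k) d[k] = dm[k];
}

// Valid cross-correlation ("convolution" in CNN usage), stride >= 1, no padding.
// x: H x W x Cin x N, w: kh x kw x Cin x Cout, b: Cout.
// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride) {
  int xd[4], wd[4];
  dims4(x, xd); dims4(w, wd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  if (wd[2] != C) stop("filter channel mismatch");
  int oh = (H - kh) / stride + 1, ow = (W - kw) / stride + 1;
  if (oh < 1 || ow < 1) stop("kernel larger than input");
  NumericVector y((R_xlen_t)oh * ow * F * N);
  y.attr("dim") = IntegerVector::create(oh, ow, F, N);
  const double* px = x.begin(); const double* pw = w.begin();
  double* py = y.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          double acc = b[f];
          int i0 = oi * stride, j0 = oj * stride;
          for (int c = 0; c < C; ++c)
            for (int kj = 0; kj < kw; ++kj) {
              const double* xc = px + idx4(i0, j0 + kj, c, n, H, W, C);
              const double* wc = pw + idx4(0, kj, c, f, kh, kw, C);
              for (int ki = 0; ki < kh; ++ki) acc += xc[ki] * wc[ki];
            }
          py[idx4(oi, oj, f, n, oh, ow, F)] = acc;
        }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  int stride) {
  int xd[4], wd[4], yd[4];
  dims4(x, xd); dims4(w, wd); dims4(dy, yd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], F = wd[3];
  int oh = yd[0], ow = yd[1];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw((R_xlen_t)kh * kw * C * F);
  dw.attr("dim") = IntegerVector::create(kh, kw, C, F);
  NumericVector db(F);
  const double* px = x.begin(); const double* pw = w.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin(); double* pdw = dw.begin();
  for (int n = 0; n < N; ++n)
    for (int f = 0; f < F; ++f)
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          double g = pdy[idx4(oi, oj, f, n, oh, ow, F)];
          if (g == 0.0) continue;
          db[f] += g;
          int i0 = oi * stride, j0 = oj * stride;
          for (int c = 0; c < C; ++c)
            for (int kj = 0; kj < kw; ++kj) {
              const double* xc = px + idx4(i0, j0 + kj, c, n, H, W, C);
              double* dxc = pdx + idx4(i0, j0 + kj, c, n, H, W, C);
              const double* wc = pw + idx4(0, kj, c, f, kh, kw, C);
              double* dwc = pdw + idx4(0, kj, c, f, kh, kw, C);
              for (int ki = 0; ki < kh; ++ki) {
                dwc[ki] += g * xc[ki];
                dxc[ki] += g * wc[ki];
              }
            }
        }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Average pooling, valid windows only (no padding).
// [[Rcpp::export]]
NumericVector cpp_pool_avg_fwd(NumericVector x, int k, int stride) {
  int xd[4];
  dims4(x, xd);
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int oh = (H - k) / stride + 1, ow = (W - k) / stride + 1;
  if (oh < 1 || ow < 1) stop("pooling window larger than input");
  NumericVector y((R_xlen_t)oh * ow * C * N);
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  const double* px = x.begin(); double* py = y.begin();
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          double acc = 0.0;
          for (int kj = 0; kj < k; ++kj) {
            const double* xc = px + idx4(oi * stride, oj * stride + kj, c, n, H, W, C);
            for (int ki = 0; ki < k; ++ki) acc += xc[ki];
          }
          py[idx4(oi, oj, c, n, oh, ow, C)] = acc * inv;
        }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_pool_avg_bwd(NumericVector dy, int H, int W, int k,
                               int stride) {
  int yd[4];
  dims4(dy, yd);
  int oh = yd[0], ow = yd[1], C = yd[2], N = yd[3];
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  const double* pdy = dy.begin(); double* pdx = dx.begin();
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          double g = pdy[idx4(oi, oj, c, n, oh, ow, C)] * inv;
          for (int kj = 0; kj < k; ++kj) {
            double* dxc = pdx + idx4(oi * stride, oj * stride + kj, c, n, H, W, C);
            for (int ki = 0; ki < k; ++ki) dxc[ki] += g;
          }
        }
  return dx;
}

// Per-point k-th nearest-neighbour thresholds for a delay embedding of u
// (dimension m, delay tau), without materialising the trajectory.
static inline double embed_dist2(const double* u, int i, int j, int m, int tau) {
  double s = 0.0;
  for (int d = 0; d < m; ++d) {
    double diff = u[i + d * tau] - u[j + d * tau];
    s += diff * diff;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_knn_eps(NumericVector u, int m, int tau, int k) {
  int L = u.size();
  int N = L - (m - 1) * tau;
  if (N < 2) stop("series too short for embedding");
  if (k > N - 1) stop("k must be <= N - 1");
  NumericVector eps(N);
  std::vector<double> row(N - 1);
  const double* pu = u.begin();
  for (int i = 0; i < N; ++i) {
    int t = 0;
    for (int j = 0; j < N; ++j) {
      if (j == i) continue;
      row[t++] = embed_dist2(pu, i, j, m, tau);
    }
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    eps[i] = std::sqrt(row[k - 1]);
  }
  return eps;
}

// Fused recurrence-plot image: embed -> per-point (or global) k-NN epsilon ->
// strict-threshold recurrence -> area-weighted resampling to size x size.
// Cell i (0-based) of the N-cell axis covers [i, i+1); pixel a covers
// [a*N/size, (a+1)*N/size); the pixel value is the area-weighted mean of the
// binary recurrences under it, so mean(image) == recurrence rate exactly.
// [[Rcpp::export]]
NumericMatrix cpp_signal_rp(NumericVector u, int m, int tau, int k, int size,
                            bool global_eps) {
  int L = u.size();
  int N = L - (m - 1) * tau;
  if (N < 2) stop("series too short for embedding");
  if (size < 1) stop("size must be >= 1");
  NumericVector eps = cpp_knn_eps(u, m, tau, k);
  if (global_eps) {
    double mu = 0.0;
    for (int i = 0; i < N; ++i) mu += eps[i];
    mu /= N;
    for (int i = 0; i < N; ++i) eps[i] = mu;
  }
  // Per-cell pixel overlap weights (each unit cell spans at most 2 pixels
  // when size <= N; when upsampling a cell spans many pixels).
  double scale = (double)size / N;
  std::vector<std::vector<std::pair<int, double> > > wmap(N);
  for (int i = 0; i < N; ++i) {
    double lo = i * scale, hi = (i + 1) * scale;
    int a0 = (int)std::floor(lo), a1 = (int)std::ceil(hi);
    if (a1 > size) a1 = size;
    for (int a = a0; a < a1; ++a) {
      double ov = std::min(hi, (double)a + 1) - std::max(lo, (double)a);
      if (ov > 0) wmap[i].push_back(std::make_pair(a, ov));
    }
  }
  NumericMatrix img(size, size);
  const double* pu = u.begin();
  for (int i = 0; i < N; ++i) {
    for (int j = 0; j < N; ++j) {
      // strict: Theta(eps - d) with Theta(0) = 0; compare on the same
      // sqrt scale as the thresholds so ties resolve identically
      if (std::sqrt(embed_dist2(pu, i, j, m, tau)) < eps[i]) {
        for (size_t ai = 0; ai < wmap[i].size(); ++ai)
          for (size_t bj = 0; bj < wmap[j].size(); ++bj)
            img(wmap[i][ai].first, wmap[j][bj].first) +=
              wmap[i][ai].second * wmap[j][bj].second;
      }
    }
  }
  // overlaps are measured in pixel units, so the accumulated sums are the
  // area-weighted means already; no further normalisation
  return img;
}
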