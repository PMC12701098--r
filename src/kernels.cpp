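// Minimal 3D CNN kernels: convolution (im2col + sgemm), 2x max-pooling and
// nearest-neighbour upsampling. Volumes are R arrays with dim (C, H, W, D),
// channel-fastest, so an im2col column is a stack of contiguous C-strips.
// Accumulation is float32; inputs/outputs cross the R boundary as doubles.
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static std::vector<float> to_float(const NumericVector& v) {
  std::vector<float> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

// Gather im2col columns for output voxels with depth index in [d0, d1).
// cols is (C*k^3) x (H*W*(d1-d0)); out-of-bounds taps stay zero (same padding).
static void im2col_chunk(const float* x, int C, int H, int W, int D,
                         int k, int d0, int d1, arma::fmat& cols) {
  const int p = k / 2;
  cols.zeros();
  for (int kd = 0; kd < k; ++kd)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int o = kh + k * (kw + k * kd);
        for (int d = d0; d < d1; ++d) {
          const int zd = d + kd - p;
          if (zd < 0 || zd >= D) continue;
          for (int w = 0; w < W; ++w) {
            const int zw = w + kw - p;
            if (zw < 0 || zw >= W) continue;
            const int zh0 = std::max(0, p - kh), zh1 = std::min(H, H + p - kh);
            for (int h = zh0; h < zh1; ++h) {
              const int zh = h + kh - p;
              const size_t col = (size_t)h + (size_t)H * ((size_t)w + (size_t)W * (d - d0));
              const float* src = x + (size_t)C * ((size_t)zh + (size_t)H * ((size_t)zw + (size_t)W * zd));
              std::memcpy(cols.colptr(col) + (size_t)C * o, src, sizeof(float) * C);
            }
          }
        }
      }
}

// Scatter-add of column gradients back onto the input volume.
static void col2im_chunk(const arma::fmat& cols, float* gx, int C, int H, int W, int D,
                         int k, int d0, int d1) {
  const int p = k / 2;
  for (int kd = 0; kd < k; ++kd)
    for (int kw = 0; kw < k; ++kw)
      for (int kh = 0; kh < k; ++kh) {
        const int o = kh + k * (kw + k * kd);
        for (int d = d0; d < d1; ++d) {
          const int zd = d + kd - p;
          if (zd < 0 || zd >= D) continue;
          for (int w = 0; w < W; ++w) {
            const int zw = w + kw - p;
            if (zw < 0 || zw >= W) continue;
            const int zh0 = std::max(0, p - kh), zh1 = std::min(H, H + p - kh);
            for (int h = zh0; h < zh1; ++h) {
              const int zh = h + kh - p;
              const size_t col = (size_t)h + (size_t)H * ((size_t)w + (size_t)W * (d - d0));
              const float* src = cols.colptr(col) + (size_t)C * o;
              float* dst = gx + (size_t)C * ((size_t)zh + (size_t)H * ((size_t)zw + (size_t)W * zd));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
}

static int chunk_depth(int C, int H, int W, int k) {
  // keep the im2col buffer near 64 MB
  double per_slice = (double)C * k * k * k * H * W * 4.0;
  int n = (int)std::max(1.0, std::floor(64e6 / per_slice));
  return n;
}

// x: (C_in,H,W,D); w: (C_out,C_in,k,k,k); b: length C_out. Stride 1, same padding.
// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], D = xd[3];
  const int Co = wd[0], k = wd[2];
  std::vector<float> xf = to_float(x), wf = to_float(w), bf = to_float(b);
  // reorder w (Co,Ci,kh,kw,kd) -> matrix Co x (Ci*k^3), column = ci + Ci*o
  const int k3 = k * k * k;
  arma::fmat Wm(Co, (size_t)C * k3);
  for (int o = 0; o < k3; ++o)
    for (int ci = 0; ci < C; ++ci)
      for (int co = 0; co < Co; ++co)
        Wm(co, (size_t)ci + (size_t)C * o) = wf[(size_t)co + (size_t)Co * ((size_t)ci + (size_t)C * o)];
  NumericVector y((R_xlen_t)Co * H * W * D);
  y.attr("dim") = IntegerVector::create(Co, H, W, D);
  const int dc = chunk_depth(C, H, W, k);
  arma::fmat cols((size_t)C * k3, (size_t)H * W * std::min(dc, D));
  for (int d0 = 0; d0 < D; d0 += dc) {
    const int d1 = std::min(D, d0 + dc);
    if ((int)cols.n_cols != H * W * (d1 - d0)) cols.set_size((size_t)C * k3, (size_t)H * W * (d1 - d0));
    im2col_chunk(xf.data(), C, H, W, D, k, d0, d1, cols);
    arma::fmat out = Wm * cols;
    double* yp = REAL(y) + (size_t)Co * H * W * d0;
    for (size_t j = 0; j < out.n_cols; ++j)
      for (int co = 0; co < Co; ++co)
        yp[(size_t)co + (size_t)Co * j] = out(co, j) + bf[co];
  }
  return y;
}

// Gradients of the same convolution. gy: (C_out,H,W,D).
// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], D = xd[3];
  const int Co = wd[0], k = wd[2], k3 = k * k * k;
  std::vector<float> xf = to_float(x), wf = to_float(w), gyf = to_float(gy);
  arma::fmat Wm(Co, (size_t)C * k3);
  for (int o = 0; o < k3; ++o)
    for (int ci = 0; ci < C; ++ci)
      for (int co = 0; co < Co; ++co)
        Wm(co, (size_t)ci + (size_t)C * o) = wf[(size_t)co + (size_t)Co * ((size_t)ci + (size_t)C * o)];
  arma::fmat GW(Co, (size_t)C * k3, arma::fill::zeros);
  arma::fvec GB(Co, arma::fill::zeros);
  std::vector<float> gxf((size_t)C * H * W * D, 0.0f);
  const int dc = chunk_depth(C, H, W, k);
  arma::fmat cols;
  for (int d0 = 0; d0 < D; d0 += dc) {
    const int d1 = std::min(D, d0 + dc);
    const size_t nc = (size_t)H * W * (d1 - d0);
    cols.set_size((size_t)C * k3, nc);
    im2col_chunk(xf.data(), C, H, W, D, k, d0, d1, cols);
    arma::fmat gym(&gyf[(size_t)Co * H * W * d0], Co, nc, false, true);
    GW += gym * cols.t();
    GB += arma::sum(gym, 1);
    arma::fmat gcols = Wm.t() * gym;
    col2im_chunk(gcols, gxf.data(), C, H, W, D, k, d0, d1);
  }
  NumericVector gx((R_xlen_t)C * H * W * D);
  gx.attr("dim") = IntegerVector::create(C, H, W, D);
  for (size_t i = 0; i < gxf.size(); ++i) REAL(gx)[i] = gxf[i];
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  for (int o = 0; o < k3; ++o)
    for (int ci = 0; ci < C; ++ci)
      for (int co = 0; co < Co; ++co)
        REAL(gw)[(size_t)co + (size_t)Co * ((size_t)ci + (size_t)C * o)] = GW(co, (size_t)ci + (size_t)C * o);
  NumericVector gb(Co);
  for (int co = 0; co < Co; ++co) gb[co] = GB(co);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; dims must be even. Returns pooled array and 1-based argmax
// indices into the input (for the backward pass).
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], D = xd[3];
  const int Ho = H / 2, Wo = W / 2, Do = D / 2;
  NumericVector y((R_xlen_t)C * Ho * Wo * Do);
  y.attr("dim") = IntegerVector::create(C, Ho, Wo, Do);
  IntegerVector idx(y.size());
  const double* xp = REAL(x);
  for (int d = 0; d < Do; ++d)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int c = 0; c < C; ++c) {
          double best = -INFINITY; size_t bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t i = (size_t)c + (size_t)C * ((size_t)(2 * h + dx) +
                          (size_t)H * ((size_t)(2 * w + dy) + (size_t)W * (2 * d + dz)));
                if (xp[i] > best) { best = xp[i]; bi = i; }
              }
          size_t j = (size_t)c + (size_t)C * ((size_t)h + (size_t)Ho * ((size_t)w + (size_t)Wo * d));
          REAL(y)[j] = best;
          idx[j] = (int)(bi + 1);
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  for (R_xlen_t j = 0; j < gy.size(); ++j) REAL(gx)[idx[j] - 1] += gy[j];
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int C = xd[0], H = xd[1], W = xd[2], D = xd[3];
  NumericVector y((R_xlen_t)C * 8 * H * W * D);
  y.attr("dim") = IntegerVector::create(C, 2 * H, 2 * W, 2 * D);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  for (int d = 0; d < 2 * D; ++d)
    for (int w = 0; w < 2 * W; ++w)
      for (int h = 0; h < 2 * H; ++h) {
        const double* src = xp + (size_t)C * ((size_t)(h / 2) + (size_t)H * ((size_t)(w / 2) + (size_t)W * (d / 2)));
        double* dst = yp + (size_t)C * ((size_t)h + (size_t)(2 * H) * ((size_t)w + (size_t)(2 * W) * d));
        std::memcpy(dst, src, sizeof(double) * C);
      }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_bwd(NumericVector gy) {
  IntegerVector yd = gy.attr("dim");
  const int C = yd[0], H2 = yd[1], W2 = yd[2], D2 = yd[3];
  const int H = H2 / 2, W = W2 / 2, D = D2 / 2;
  NumericVector gx((R_xlen_t)C * H * W * D);
  gx.attr("dim") = IntegerVector::create(C, H, W, D);
  const double* gp = REAL(gy);
  double* xp = REAL(gx);
  for (int d = 0; d < D2; ++d)
    for (int w = 0; w < W2; ++w)
      for (int h = 0; h < H2; ++h) {
        const double* src = gp + (size_t)C * ((size_t)h + (size_t)H2 * ((size_t)w + (size_t)W2 * d));
        double* dst = xp + (size_t)C * ((size_t)(h / 2) + (size_t)H * ((size_t)(w / 2) + (size_t)W * (d / 2)));
        for (int c = 0; c < C; ++c) dst[c] += src[c];
      }
  return gx;
}

// Connected component of voxels sharing lab, grown from a seed (0-based flat
// index) under 6-connectivity. labels: (H,W,D) integer array. Returns a logical
// mask of the component.
// [[Rcpp::export]]
LogicalVector cpp_region_grow(IntegerVector labels, int seed0) {
  IntegerVector ld = labels.attr("dim");
  const int H = ld[0], W = ld[1], D = ld[2];
  const int lab = labels[seed0];
  LogicalVector mask((R_xlen_t)H * W * D);
  mask.attr("dim") = ld;
  std::vector<int> stack;
  stack.push_back(seed0);
  mask[seed0] = true;
  while (!stack.empty()) {
    const int v = stack.back(); stack.pop_back();
    const int h = v % H, w = (v / H) % W, d = v / (H * W);
    const int nh[6] = { h - 1, h + 1, h, h, h, h };
    const int nw[6] = { w, w, w - 1, w + 1, w, w };
    const int nd[6] = { d, d, d, d, d - 1, d + 1 };
    for (int i = 0; i < 6; ++i) {
      if (nh[i] < 0 || nh[i] >= H || nw[i] < 0 || nw[i] >= W || nd[i] < 0 || nd[i] >= D) continue;
      const int u = nh[i] + H * (nw[i] + W * nd[i]);
      if (!mask[u] && labels[u] == lab) { mask[u] = true; stack.push_back(u); }
    }
  }
  return mask;
}

// L1 spatial-continuity loss and its gradient on a (q,H,W,D) response map:
// mean absolute forward difference along the three spatial axes. With
// axis_sum = false all (channel, pair) terms are pooled into one mean; with
// axis_sum = true each axis is averaged separately and the three means are
// summed. Double precision to match the R-side oracle.
// [[Rcpp::export]]
List cpp_cont_loss_grad(NumericVector resp, bool want_grad, bool axis_sum = false) {
  IntegerVector rd = resp.attr("dim");
  const int q = rd[0], H = rd[1], W = rd[2], D = rd[3];
  const double ph = (double)(H - 1) * W * D, pw = (double)H * (W - 1) * D,
               pd = (double)H * W * (D - 1);
  if (ph + pw + pd <= 0) stop("degenerate input: all spatial dimensions have extent 1");
  // per-term weights for each axis under the two reductions
  const double pooled = q * (ph + pw + pd);
  const double wh = axis_sum ? (ph > 0 ? 1.0 / (q * ph) : 0.0) : 1.0 / pooled;
  const double ww = axis_sum ? (pw > 0 ? 1.0 / (q * pw) : 0.0) : 1.0 / pooled;
  const double wd = axis_sum ? (pd > 0 ? 1.0 / (q * pd) : 0.0) : 1.0 / pooled;
  const double* x = REAL(resp);
  NumericVector grad;
  double* g = nullptr;
  if (want_grad) {
    grad = NumericVector(resp.size());
    grad.attr("dim") = rd;
    g = REAL(grad);
  }
  long double th = 0.0L, tw = 0.0L, td = 0.0L;
  const size_t sh = q, sw = (size_t)q * H, sd = (size_t)q * H * W;
  for (int d = 0; d < D; ++d)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        const size_t base = sh * h + sw * w + sd * d;
        for (int c = 0; c < q; ++c) {
          const size_t i = base + c;
          const double v = x[i];
          if (h + 1 < H) {
            const double df = x[i + sh] - v;
            th += std::fabs(df);
            if (want_grad && df != 0) { const double s = (df > 0 ? wh : -wh); g[i + sh] += s; g[i] -= s; }
          }
          if (w + 1 < W) {
            const double df = x[i + sw] - v;
            tw += std::fabs(df);
            if (want_grad && df != 0) { const double s = (df > 0 ? ww : -ww); g[i + sw] += s; g[i] -= s; }
          }
          if (d + 1 < D) {
            const double df = x[i + sd] - v;
            td += std::fabs(df);
            if (want_grad && df != 0) { const double s = (df > 0 ? wd : -wd); g[i + sd] += s; g[i] -= s; }
          }
        }
      }
  const double loss = (double)(th * (long double)wh + tw * (long double)ww + td * (long double)wd);
  List out = List::create(_["loss"] = loss);
  if (want_grad) out["grad"] = grad;
  return out;
}
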