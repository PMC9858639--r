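// Minimal convolutional-network primitives for the two-branch
// encoder-decoder: 3x3 same-padding convolution (dense and depthwise)
// and 2x2 max pooling, each with its exact gradient. Feature maps are
// H x W x C cubes; 3x3 kernels are stored as (9*Cin) x Cout matrices
// with patch ordering c*9 + (dy+1)*3 + (dx+1), so convolution is an
// im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword k = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          double* dst = out.colptr(k) + j * H;
          const double* src = xc.colptr(js);
          int r0 = std::max(0, -dy), r1 = std::min((int)H, (int)H - dy);
          for (int i = r0; i < r1; ++i) dst[i] = src[i + dy];
        }
      }
    }
  }
  return out;
}

static cube col2im3(const mat& g, uword H, uword W, uword C) {
  cube out(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& oc = out.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        uword k = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const double* src = g.colptr(k) + j * H;
          double* dst = oc.colptr(js);
          int r0 = std::max(0, -dy), r1 = std::min((int)H, (int)H - dy);
          for (int i = r0; i < r1; ++i) dst[i + dy] += src[i];
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube conv3_fwd(const arma::cube& x, const arma::mat& w,
                     const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  mat y = im2col3(x) * w;
  y.each_row() += b.t();
  return cube(y.memptr(), H, W, Cout);
}

// [[Rcpp::export]]
Rcpp::List conv3_bwd(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat G(const_cast<double*>(gy.memptr()), H * W, gy.n_slices, false, true);
  mat xc = im2col3(x);
  mat dW = xc.t() * G;
  vec db = sum(G, 0).t();
  mat dXc = G * w.t();
  cube dx = col2im3(dXc, H, W, C);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dW,
                            Rcpp::Named("db") = db);
}

// depthwise 3x3 convolution; k is 3 x 3 x C
// [[Rcpp::export]]
arma::cube dwconv3_fwd(const arma::cube& x, const arma::cube& k,
                       const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    mat& yc = y.slice(c);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        double kv = k(dy + 1, dx + 1, c);
        if (kv == 0) continue;
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          double* dst = yc.colptr(j);
          const double* src = xc.colptr(js);
          int r0 = std::max(0, -dy), r1 = std::min((int)H, (int)H - dy);
          for (int i = r0; i < r1; ++i) dst[i] += kv * src[i + dy];
        }
      }
    yc += b(c);
  }
  return y;
}

// [[Rcpp::export]]
Rcpp::List dwconv3_bwd(const arma::cube& x, const arma::cube& k,
                       const arma::cube& gy) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube dx(H, W, C, fill::zeros);
  cube dk(3, 3, C, fill::zeros);
  vec db(C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    const mat& gc = gy.slice(c);
    mat& dxc = dx.slice(c);
    db(c) = accu(gc);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx_ = -1; dx_ <= 1; ++dx_) {
        double kv = k(dy + 1, dx_ + 1, c);
        double acc = 0.0;
        for (uword j = 0; j < W; ++j) {
          int js = (int)j + dx_;
          if (js < 0 || js >= (int)W) continue;
          const double* g = gc.colptr(j);
          const double* src = xc.colptr(js);
          double* d = dxc.colptr(js);
          int r0 = std::max(0, -dy), r1 = std::min((int)H, (int)H - dy);
          for (int i = r0; i < r1; ++i) {
            acc += g[i] * src[i + dy];
            d[i + dy] += kv * g[i];
          }
        }
        dk(dy + 1, dx_ + 1, c) = acc;
      }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dk") = dk,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; H and W must be even.
// [[Rcpp::export]]
Rcpp::List maxpool2_fwd(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const uword Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C);  // linear index into the input cube
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (uword j = 0; j < Wo; ++j)
      for (uword i = 0; i < Ho; ++i) {
        uword r = 2 * i, s = 2 * j;
        double best = xc(r, s); uword bi = r, bj = s;
        if (xc(r + 1, s) > best) { best = xc(r + 1, s); bi = r + 1; bj = s; }
        if (xc(r, s + 1) > best) { best = xc(r, s + 1); bi = r; bj = s + 1; }
        if (xc(r + 1, s + 1) > best) { best = xc(r + 1, s + 1); bi = r + 1; bj = s + 1; }
        y(i, j, c) = best;
        idx(i, j, c) = c * H * W + bj * H + bi;
      }
  }
  Rcpp::IntegerVector iv(idx.n_elem);
  for (uword t = 0; t < idx.n_elem; ++t) iv[t] = (int)idx(t) + 1; // 1-based
  iv.attr("dim") = Rcpp::IntegerVector::create(Ho, Wo, C);
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = iv);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd(const Rcpp::IntegerVector& idx, const arma::cube& gy,
                        int H, int W) {
  const uword C = gy.n_slices;
  cube dx((uword)H, (uword)W, C, fill::zeros);
  const int n = idx.size();
  const double* g = gy.memptr();
  double* d = dx.memptr();
  for (int t = 0; t < n; ++t) d[idx[t] - 1] += g[t];
  return dx;
}
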