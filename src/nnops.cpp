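// Low-level tensor ops for the CNN layers: 2-D convolution (im2col + GEMM),
// zero/reflection padding with matching gradient folding, and 2x2 max pooling.
// Tensors are H x W x C arma::cubes (column-major, row index fastest),
// weights are (kh*kw*Cin) x Cout matrices flattened in (ki, kj, c) order,
// i.e. the natural flattening of an R array with dim c(kh, kw, cin, cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using namespace Rcpp;

// mirror-without-edge-repeat index (reflect101)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

static cube pad_cube(const cube& x, int p, bool reflect) {
  if (p == 0) return x;
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube xp(H + 2 * p, W + 2 * p, C, fill::zeros);
  if (!reflect) {
    xp.subcube(p, p, 0, p + H - 1, p + W - 1, C - 1) = x;
    return xp;
  }
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W + 2 * p; ++j) {
      const int sj = reflect_idx(j - p, W);
      for (int i = 0; i < H + 2 * p; ++i)
        xp(i, j, c) = x(reflect_idx(i - p, H), sj, c);
    }
  return xp;
}

// fold gradient of the padded tensor back onto the unpadded one
static cube unpad_grad(const cube& gp, int p, int H, int W, bool reflect) {
  const int C = gp.n_slices;
  if (p == 0) return gp;
  cube g(H, W, C, fill::zeros);
  if (!reflect) {
    g = gp.subcube(p, p, 0, p + H - 1, p + W - 1, C - 1);
    return g;
  }
  for (int c = 0; c < C; ++c)
    for (unsigned j = 0; j < gp.n_cols; ++j) {
      const int sj = reflect_idx((int)j - p, W);
      for (unsigned i = 0; i < gp.n_rows; ++i)
        g(reflect_idx((int)i - p, H), sj, c) += gp(i, j, c);
    }
  return g;
}

static mat im2col(const cube& xp, int kh, int kw, int stride, int OH, int OW) {
  const int C = xp.n_slices;
  mat cols(kh * kw * C, OH * OW);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int jj = ow * stride + kj;
          double* dst = cols.colptr(ow * OH) + r;
          for (int oh = 0; oh < OH; ++oh)
            dst[(size_t)oh * cols.n_rows] = xp(oh * stride + ki, jj, c);
        }
      }
  return cols;
}

static void col2im_add(cube& gp, const mat& dcols, int kh, int kw, int stride,
                       int OH, int OW) {
  const int C = gp.n_slices;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < kw; ++kj)
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int ow = 0; ow < OW; ++ow) {
          const int jj = ow * stride + kj;
          const double* src = dcols.colptr(ow * OH) + r;
          for (int oh = 0; oh < OH; ++oh)
            gp(oh * stride + ki, jj, c) += src[(size_t)oh * dcols.n_rows];
        }
      }
}

// [[Rcpp::export]]
arma::cube cpp_conv_fw(const arma::cube& x, const arma::mat& w,
                       const arma::vec& b, int kh, int kw, int stride,
                       int pad, bool reflect) {
  cube xp = pad_cube(x, pad, reflect);
  const int OH = ((int)xp.n_rows - kh) / stride + 1;
  const int OW = ((int)xp.n_cols - kw) / stride + 1;
  const int Cout = w.n_cols;
  mat cols = im2col(xp, kh, kw, stride, OH, OW);
  mat y = w.t() * cols;            // Cout x (OH*OW)
  y.each_col() += b;
  cube out(OH, OW, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c), OH, OW);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv_bw(const arma::cube& x, const arma::mat& w,
                       const arma::cube& dy, int kh, int kw, int stride,
                       int pad, bool reflect) {
  cube xp = pad_cube(x, pad, reflect);
  const int OH = dy.n_rows, OW = dy.n_cols, Cout = dy.n_slices;
  mat dym(Cout, OH * OW);
  for (int c = 0; c < Cout; ++c)
    dym.row(c) = reshape(dy.slice(c), 1, OH * OW);
  mat cols = im2col(xp, kh, kw, stride, OH, OW);
  mat dw = cols * dym.t();         // K x Cout
  vec db = sum(dym, 1);
  mat dcols = w * dym;             // K x (OH*OW)
  cube gp(xp.n_rows, xp.n_cols, xp.n_slices, fill::zeros);
  col2im_add(gp, dcols, kh, kw, stride, OH, OW);
  cube dx = unpad_grad(gp, pad, x.n_rows, x.n_cols, reflect);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2, even H and W assumed (checked by caller)
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& x) {
  const int OH = x.n_rows / 2, OW = x.n_cols / 2, C = x.n_slices;
  cube y(OH, OW, C);
  ucube idx(OH, OW, C);            // winner offset 0..3: (di, dj) = (k%2, k/2)
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        double best = x(2 * oh, 2 * ow, c);
        int bi = 0;
        for (int k = 1; k < 4; ++k) {
          const double v = x(2 * oh + (k % 2), 2 * ow + (k / 2), c);
          if (v > best) { best = v; bi = k; }
        }
        y(oh, ow, c) = best;
        idx(oh, ow, c) = bi;
      }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::ucube& idx, const arma::cube& dy,
                          int H, int W) {
  const int OH = dy.n_rows, OW = dy.n_cols, C = dy.n_slices;
  cube dx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int ow = 0; ow < OW; ++ow)
      for (int oh = 0; oh < OH; ++oh) {
        const int k = idx(oh, ow, c);
        dx(2 * oh + (k % 2), 2 * ow + (k / 2), c) += dy(oh, ow, c);
      }
  return dx;
}
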