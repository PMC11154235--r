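// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

// Stride-1 2D convolution kernels for the artefact-reduction network.
// Activations are cubes (H x W x C), matching R's array(H, W, C) layout.
// Weights are passed as a (k*k*Cin) x Cout matrix whose row order matches
// as.vector(W[k, k, Cin, Cout]) in R: dy fastest, then dx, then input channel.
// "same" output size requires pad = (k - 1) / 2 for odd k; pad = 0 gives a
// valid 1x1 convolution when k = 1.

static mat im2col(const cube &x, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat cols(H * W, (uword)k * k * C, fill::zeros);
  for (int c = 0; c < C; c++) {
    const mat &xc = x.slice(c);
    for (int dx = 0; dx < k; dx++) {
      for (int dy = 0; dy < k; dy++) {
        const uword col = (uword)(c * k + dx) * k + dy;
        double *out = cols.colptr(col);
        for (int j = 0; j < W; j++) {
          const int sj = j + dx - pad;
          if (sj < 0 || sj >= W) continue;
          const double *src = xc.colptr(sj);
          double *o = out + (size_t)j * H;
          const int ilo = std::max(0, pad - dy);
          const int ihi = std::min(H - 1, H - 1 + pad - dy);
          for (int i = ilo; i <= ihi; i++) o[i] = src[i + dy - pad];
        }
      }
    }
  }
  return cols;
}

static void col2im_add(cube &dx_out, const mat &dcols, int k, int pad) {
  const int H = dx_out.n_rows, W = dx_out.n_cols, C = dx_out.n_slices;
  for (int c = 0; c < C; c++) {
    mat &xc = dx_out.slice(c);
    for (int dxk = 0; dxk < k; dxk++) {
      for (int dy = 0; dy < k; dy++) {
        const uword col = (uword)(c * k + dxk) * k + dy;
        const double *dc = dcols.colptr(col);
        for (int j = 0; j < W; j++) {
          const int sj = j + dxk - pad;
          if (sj < 0 || sj >= W) continue;
          double *dst = xc.colptr(sj);
          const double *d = dc + (size_t)j * H;
          const int ilo = std::max(0, pad - dy);
          const int ihi = std::min(H - 1, H - 1 + pad - dy);
          for (int i = ilo; i <= ihi; i++) dst[i + dy - pad] += d[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv2d_forward(const arma::cube &x, const arma::mat &w2d,
                              const arma::vec &b, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int cout = w2d.n_cols;
  mat y2d;
  if (k == 1) {
    mat x2d(const_cast<double *>(x.memptr()), (uword)H * W, x.n_slices, false, true);
    y2d = x2d * w2d;
  } else {
    y2d = im2col(x, k, pad) * w2d;
  }
  y2d.each_row() += b.t();
  cube y(H, W, cout);
  std::memcpy(y.memptr(), y2d.memptr(), sizeof(double) * y2d.n_elem);
  return y;
}

// Returns gradients wrt input, weights and bias for one activation cube.
// [[Rcpp::export]]
Rcpp::List cpp_conv2d_backward(const arma::cube &x, const arma::mat &w2d,
                               const arma::cube &dy, int k, int pad) {
  const int H = x.n_rows, W = x.n_cols;
  const int cin = x.n_slices, cout = dy.n_slices;
  mat dy2d(const_cast<double *>(dy.memptr()), (uword)H * W, cout, false, true);
  mat dw;
  cube dx(H, W, cin, fill::zeros);
  if (k == 1) {
    mat x2d(const_cast<double *>(x.memptr()), (uword)H * W, cin, false, true);
    dw = x2d.t() * dy2d;
    mat dx2d = dy2d * w2d.t();
    std::memcpy(dx.memptr(), dx2d.memptr(), sizeof(double) * dx2d.n_elem);
  } else {
    mat cols = im2col(x, k, pad);
    dw = cols.t() * dy2d;
    mat dcols = dy2d * w2d.t();
    col2im_add(dx, dcols, k, pad);
  }
  vec db = sum(dy2d, 0).t();
  return Rcpp::List::create(Rcpp::_["dx"] = dx, Rcpp::_["dw"] = dw,
                            Rcpp::_["db"] = db);
}
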