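#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// 2D convolution primitives for the in-package autoencoders, written as
// im2col + BLAS GEMM. Activations are cubes (H, W, C); weights are
// (k*k*Cin) x Cout with rows ordered (di, dj, cin) column-major, i.e.
// row = di + k * dj + k * k * cin. Zero padding, square kernels.

static arma::mat im2col(const arma::cube& x, int k, int stride, int pad,
                        int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(Ho * Wo, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int colix = di + k * dj + k * k * c;
        double* dst = cols.colptr(colix);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * stride + dj - pad;
          if (jin < 0 || jin >= W) continue;
          const double* src = x.slice_colptr(c, jin);
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * stride + di - pad;
            if (iin < 0 || iin >= H) continue;
            dst[io + Ho * jo] = src[iin];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
List nn_conv_forward(const arma::cube& x, const arma::mat& W,
                     const arma::vec& b, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (Wd + 2 * pad - k) / stride + 1;
  const int Cout = W.n_cols;
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat out = cols * W;
  out.each_row() += b.t();
  arma::cube y(Ho, Wo, Cout);
  std::memcpy(y.memptr(), out.memptr(), sizeof(double) * out.n_elem);
  return List::create(_["out"] = y);
}

// [[Rcpp::export]]
List nn_conv_backward(const arma::cube& x, const arma::mat& W,
                      const arma::cube& dout, int k, int stride, int pad) {
  const int H = x.n_rows, Wd = x.n_cols, C = x.n_slices;
  const int Ho = dout.n_rows, Wo = dout.n_cols, Cout = dout.n_slices;
  arma::mat cols = im2col(x, k, stride, pad, Ho, Wo);
  arma::mat dout_m(const_cast<double*>(dout.memptr()), Ho * Wo, Cout, false);
  arma::mat dW = cols.t() * dout_m;
  arma::vec db = arma::sum(dout_m, 0).t();
  arma::mat dcols = dout_m * W.t();

  // col2im: scatter-add the column gradients back onto the input grid
  arma::cube dx(H, Wd, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int colix = di + k * dj + k * k * c;
        const double* src = dcols.colptr(colix);
        for (int jo = 0; jo < Wo; ++jo) {
          const int jin = jo * stride + dj - pad;
          if (jin < 0 || jin >= Wd) continue;
          double* dst = dx.slice_colptr(c, jin);
          for (int io = 0; io < Ho; ++io) {
            const int iin = io * stride + di - pad;
            if (iin < 0 || iin >= H) continue;
            dst[iin] += src[io + Ho * jo];
          }
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
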