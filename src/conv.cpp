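// 3x3 convolution primitives for the wavelet-domain residual network.
// Layout: activations are H x W x C cubes (column-major, matching R arrays);
// weights for one layer are a (C_out x 9*C_in) matrix whose row r holds the
// kernel for output channel r, flattened as (c_in * 9) + (ky*3 + kx) with
// ky, kx in {0,1,2} (offset -1..1). Replicate (edge) padding, stride 1, so
// spatial size is preserved.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Gather 3x3 neighbourhoods (replicate padded) into a (9*C x H*W) matrix.
static mat im2col3(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(9 * C, (size_t)H * W);
  for (int c = 0; c < C; ++c) {
    const mat& ch = x.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int r = c * 9 + (ky + 1) * 3 + (kx + 1);
        for (int j = 0; j < W; ++j) {
          const int jj = clampi(j + kx, 0, W - 1);
          const size_t col0 = (size_t)j * H;
          for (int i = 0; i < H; ++i) {
            out(r, col0 + i) = ch(clampi(i + ky, 0, H - 1), jj);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add a (9*C x H*W) matrix back onto an image.
static cube col2im3(const mat& cols, int H, int W, int C) {
  cube g(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ch = g.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int r = c * 9 + (ky + 1) * 3 + (kx + 1);
        for (int j = 0; j < W; ++j) {
          const int jj = clampi(j + kx, 0, W - 1);
          const size_t col0 = (size_t)j * H;
          for (int i = 0; i < H; ++i) {
            ch(clampi(i + ky, 0, H - 1), jj) += cols(r, col0 + i);
          }
        }
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
arma::cube conv3x3_forward(const arma::cube& x, const arma::mat& w,
                           const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_rows;
  if ((int)w.n_cols != 9 * (int)x.n_slices)
    Rcpp::stop("weight matrix does not match input channel count");
  if ((int)b.n_elem != Cout)
    Rcpp::stop("bias length does not match output channel count");
  mat cols = im2col3(x);
  mat y = w * cols;          // Cout x H*W
  y.each_col() += b;
  cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c)
    out.slice(c) = reshape(y.row(c), H, W);
  return out;
}

// [[Rcpp::export]]
Rcpp::List conv3x3_backward(const arma::cube& x, const arma::mat& w,
                            const arma::cube& gout) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = gout.n_slices;
  if ((int)gout.n_rows != H || (int)gout.n_cols != W)
    Rcpp::stop("gradient spatial shape does not match input");
  mat G(Cout, (size_t)H * W);
  for (int c = 0; c < Cout; ++c)
    G.row(c) = vectorise(gout.slice(c)).t();
  mat cols = im2col3(x);
  mat gw = G * cols.t();                 // Cout x 9*Cin
  vec gb = sum(G, 1);
  mat gcols = w.t() * G;                 // 9*Cin x H*W
  cube gin = col2im3(gcols, H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("gx") = gin,
                            Rcpp::Named("gw") = gw,
                            Rcpp::Named("gb") = gb);
}
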