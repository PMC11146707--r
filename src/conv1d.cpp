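// Dilated 1-D convolution, im2col formulation.
//
// Tensor layout (column-major, matching R arrays):
//   signals  x : (length, channels, batch)      arma::cube
//   weights  w : (k, in_channels, out_channels) arma::cube
// The im2col matrix for one batch slice is (L_out x k*C_in), with column
// index (c-1)*k + i for tap i of input channel c, so a column-major reshape
// of w to (k*C_in x C_out) lines up with it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline int out_length(int L, int k, int stride, int dil,
                             int pad_l, int pad_r) {
  int span = (k - 1) * dil;              // distance first..last tap
  int Lp = L + pad_l + pad_r;
  if (Lp < span + 1) return 0;
  return (Lp - span - 1) / stride + 1;
}

static void im2col(const mat& xs, mat& M, int k, int stride, int dil,
                   int pad_l) {
  const int L = xs.n_rows, Cin = xs.n_cols, Lout = M.n_rows;
  for (int c = 0; c < Cin; ++c) {
    for (int i = 0; i < k; ++i) {
      const int col = c * k + i;
      for (int t = 0; t < Lout; ++t) {
        const int src = t * stride + i * dil - pad_l;
        M(t, col) = (src >= 0 && src < L) ? xs(src, c) : 0.0;
      }
    }
  }
}

// [[Rcpp::export(name = ".conv1d_forward")]]
arma::cube conv1d_forward_cpp(const arma::cube& x, const arma::cube& w,
                              const arma::vec& bias, int stride, int dil,
                              int pad_l, int pad_r) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = w.n_rows, Cout = w.n_slices;
  if ((int)w.n_cols != Cin)
    Rcpp::stop("weight in_channels (%d) != input channels (%d)",
               (int)w.n_cols, Cin);
  const int Lout = out_length(L, k, stride, dil, pad_l, pad_r);
  if (Lout <= 0)
    Rcpp::stop("input length %d too short for kernel span %d with given padding",
               L, (k - 1) * dil + 1);
  // (k*Cin x Cout) view of w; both are column-major so memory lines up
  const mat W2(const_cast<double*>(w.memptr()), k * Cin, Cout, false, true);
  cube y(Lout, Cout, B);
  mat M(Lout, k * Cin);
  for (int b = 0; b < B; ++b) {
    im2col(x.slice(b), M, k, stride, dil, pad_l);
    y.slice(b) = M * W2;
    y.slice(b).each_row() += bias.t();
  }
  return y;
}

// [[Rcpp::export(name = ".conv1d_backward")]]
Rcpp::List conv1d_backward_cpp(const arma::cube& x, const arma::cube& w,
                               const arma::cube& dy, int stride, int dil,
                               int pad_l, int pad_r) {
  const int L = x.n_rows, Cin = x.n_cols, B = x.n_slices;
  const int k = w.n_rows, Cout = w.n_slices;
  const int Lout = dy.n_rows;
  const mat W2(const_cast<double*>(w.memptr()), k * Cin, Cout, false, true);
  cube dx(L, Cin, B, fill::zeros);
  mat dW2(k * Cin, Cout, fill::zeros);
  vec db(Cout, fill::zeros);
  mat M(Lout, k * Cin);
  for (int b = 0; b < B; ++b) {
    im2col(x.slice(b), M, k, stride, dil, pad_l);
    const mat& dys = dy.slice(b);
    dW2 += M.t() * dys;
    db += sum(dys, 0).t();
    mat dM = dys * W2.t();           // (Lout x k*Cin)
    mat& dxs = dx.slice(b);
    for (int c = 0; c < Cin; ++c) {
      for (int i = 0; i < k; ++i) {
        const int col = c * k + i;
        for (int t = 0; t < Lout; ++t) {
          const int src = t * stride + i * dil - pad_l;
          if (src >= 0 && src < L) dxs(src, c) += dM(t, col);
        }
      }
    }
  }
  cube dw(k, Cin, Cout);
  std::memcpy(dw.memptr(), dW2.memptr(), sizeof(double) * k * Cin * Cout);
  return Rcpp::List::create(Rcpp::Named("dx") = dx,
                            Rcpp::Named("dw") = dw,
                            Rcpp::Named("db") = db);
}
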