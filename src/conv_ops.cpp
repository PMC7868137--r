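// Low-level convolution rearrangements. Feature maps are stored as
// (h*w) x channels matrices, column-major over (row, col) positions, so a
// column is exactly the memory of one h x w image plane.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static inline int out_side(int n, int k, int stride, int pad, int dil) {
  int keff = (k - 1) * dil + 1;
  return (n + 2 * pad - keff) / stride + 1;
}

// Unfold x into a (oh*ow) x (k*k*c) matrix of receptive-field columns.
// Column order: channel-major, then kernel column, then kernel row, matching
// the weight layout used on the R side.
// [[Rcpp::export]]
arma::mat im2col_cpp(const arma::mat& x, int h, int w,
                     int k, int stride, int pad, int dil) {
  const int c = x.n_cols;
  const int oh = out_side(h, k, stride, pad, dil);
  const int ow = out_side(w, k, stride, pad, dil);
  if (oh < 1 || ow < 1)
    Rcpp::stop("convolution output would be empty (input %d, kernel %d)", h, k);
  arma::mat out(oh * ow, (arma::uword)k * k * c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    const double* xc = x.colptr(ch);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        double* o = out.colptr((arma::uword)ch * k * k + kj * k + ki);
        for (int oj = 0; oj < ow; ++oj) {
          const int ij = oj * stride - pad + kj * dil;
          if (ij < 0 || ij >= w) continue;
          const double* src = xc + (arma::uword)ij * h;
          double* dst = o + (arma::uword)oj * oh;
          for (int oi = 0; oi < oh; ++oi) {
            const int ii = oi * stride - pad + ki * dil;
            if (ii < 0 || ii >= h) continue;
            dst[oi] = src[ii];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add columns back onto an (h*w) x c image.
// [[Rcpp::export]]
arma::mat col2im_cpp(const arma::mat& cols, int h, int w, int c,
                     int k, int stride, int pad, int dil) {
  const int oh = out_side(h, k, stride, pad, dil);
  const int ow = out_side(w, k, stride, pad, dil);
  if ((arma::uword)oh * ow != cols.n_rows ||
      (arma::uword)k * k * c != cols.n_cols)
    Rcpp::stop("col2im: column matrix shape inconsistent with geometry");
  arma::mat out((arma::uword)h * w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch) {
    double* xc = out.colptr(ch);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const double* o = cols.colptr((arma::uword)ch * k * k + kj * k + ki);
        for (int oj = 0; oj < ow; ++oj) {
          const int ij = oj * stride - pad + kj * dil;
          if (ij < 0 || ij >= w) continue;
          double* dst = xc + (arma::uword)ij * h;
          const double* src = o + (arma::uword)oj * oh;
          for (int oi = 0; oi < oh; ++oi) {
            const int ii = oi * stride - pad + ki * dil;
            if (ii < 0 || ii >= h) continue;
            dst[ii] += src[oi];
          }
        }
      }
    }
  }
  return out;
}

// In-place Adam update. The caller guarantees p, m, v are solely owned by
// the layer environment (they are allocated there and never aliased).
// [[Rcpp::export]]
void adam_update_cpp(Rcpp::NumericVector p, Rcpp::NumericVector m,
                     Rcpp::NumericVector v, Rcpp::NumericVector g,
                     double lr, double b1, double b2, double eps,
                     double c1, double c2) {
  const R_xlen_t n = p.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
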