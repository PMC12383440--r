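// Minimal 2-D convolution kernels (im2col + GEMM) backing the light
// trainable segmentation model. Layout conventions:
//   images/feature maps: arma::cube (H, W, C)  == R array dim c(H, W, C)
//   kernels: arma::mat (kh*kw*Cin, Cout), flattened column-major from an
//            R array dim c(kh, kw, Cin, Cout)
// Zero padding, square stride. All loops are deterministic (single thread).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& X, int kh, int kw,
                        int stride, int pad, int Ho, int Wo) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  arma::mat M(Ho * (long)Wo, (long)kh * kw * Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const long col = ki + (long)kh * kj + (long)kh * kw * c;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            M(oi + (long)Ho * oj, col) = X(i, j, c);
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv2dFwd")]]
arma::cube conv2d_fwd(const arma::cube& X, const arma::mat& W,
                      const arma::vec& b, int kh, int kw,
                      int stride, int pad) {
  const int H = X.n_rows, Wd = X.n_cols;
  const int Ho = (H + 2 * pad - kh) / stride + 1;
  const int Wo = (Wd + 2 * pad - kw) / stride + 1;
  const int Cout = W.n_cols;
  arma::mat M = im2col(X, kh, kw, stride, pad, Ho, Wo);
  arma::mat Y = M * W;
  Y.each_row() += b.t();
  arma::cube out(Ho, Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    out.slice(co) = arma::reshape(Y.col(co), Ho, Wo);
  return out;
}

// [[Rcpp::export(name = ".conv2dBwd")]]
List conv2d_bwd(const arma::cube& X, const arma::mat& W,
                const arma::cube& dY, int kh, int kw,
                int stride, int pad) {
  const int H = X.n_rows, Wd = X.n_cols, Cin = X.n_slices;
  const int Ho = dY.n_rows, Wo = dY.n_cols, Cout = dY.n_slices;
  arma::mat M = im2col(X, kh, kw, stride, pad, Ho, Wo);
  arma::mat dYm(Ho * (long)Wo, Cout);
  for (int co = 0; co < Cout; ++co)
    dYm.col(co) = arma::vectorise(dY.slice(co));
  arma::mat dW = M.t() * dYm;
  arma::vec db = arma::sum(dYm, 0).t();
  arma::mat dM = dYm * W.t();
  arma::cube dX(H, Wd, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const long col = ki + (long)kh * kj + (long)kh * kw * c;
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= Wd) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            dX(i, j, c) += dM(oi + (long)Ho * oj, col);
          }
        }
      }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dW,
                      Named("db") = db);
}

// Pairwise minimum Euclidean distances from each row-point in A to the
// nearest row-point in B; points are (row, col) pixel coordinates.
// [[Rcpp::export(name = ".minDistances")]]
arma::vec min_distances(const arma::mat& A, const arma::mat& B) {
  arma::vec out(A.n_rows);
  for (arma::uword i = 0; i < A.n_rows; ++i) {
    double best = arma::datum::inf;
    const double ai = A(i, 0), aj = A(i, 1);
    for (arma::uword k = 0; k < B.n_rows; ++k) {
      const double di = ai - B(k, 0), dj = aj - B(k, 1);
      const double d2 = di * di + dj * dj;
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
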