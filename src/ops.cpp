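// Low-level volumetric kernels backing the network and boundary metrics.
// Feature tensors are channel-first arrays dim = c(C, X, Y, Z) in R's
// column-major layout: index = c + C*(x + X*(y + Y*z)).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Unfold a padded volume into the (C*k^3 x N) column matrix of a
// same-padded, stride-1 3D convolution.  Row order is offset-major:
// row = c + C*o with o = (dx+1) + k*((dy+1) + k*(dz+1)) for k = 3.
// [[Rcpp::export]]
arma::mat cpp_vol2col(const arma::vec& x, int C, int X, int Y, int Z, int k) {
  const int pad = (k - 1) / 2;
  const int K3 = k * k * k;
  const long N = (long)X * Y * Z;
  arma::mat col(C * K3, N, arma::fill::zeros);
  for (int dz = 0; dz < k; ++dz) {
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int o = dx + k * (dy + k * dz);
        for (int z = 0; z < Z; ++z) {
          const int zz = z + dz - pad;
          if (zz < 0 || zz >= Z) continue;
          for (int y = 0; y < Y; ++y) {
            const int yy = y + dy - pad;
            if (yy < 0 || yy >= Y) continue;
            for (int xx0 = 0; xx0 < X; ++xx0) {
              const int xx = xx0 + dx - pad;
              if (xx < 0 || xx >= X) continue;
              const long n = xx0 + (long)X * (y + (long)Y * z);
              const long src = (long)C * (xx + (long)X * (yy + (long)Y * zz));
              double* dst = col.colptr(n) + (long)C * o;
              const double* sp = x.memptr() + src;
              for (int c = 0; c < C; ++c) dst[c] = sp[c];
            }
          }
        }
      }
    }
  }
  return col;
}

// Fold a column matrix back into a volume by summation (adjoint of
// cpp_vol2col); used for the gradient with respect to the conv input.
// [[Rcpp::export]]
arma::vec cpp_col2vol(const arma::mat& col, int C, int X, int Y, int Z, int k) {
  const int pad = (k - 1) / 2;
  const long N = (long)X * Y * Z;
  arma::vec x((long)C * N, arma::fill::zeros);
  for (int dz = 0; dz < k; ++dz) {
    for (int dy = 0; dy < k; ++dy) {
      for (int dx = 0; dx < k; ++dx) {
        const int o = dx + k * (dy + k * dz);
        for (int z = 0; z < Z; ++z) {
          const int zz = z + dz - pad;
          if (zz < 0 || zz >= Z) continue;
          for (int y = 0; y < Y; ++y) {
            const int yy = y + dy - pad;
            if (yy < 0 || yy >= Y) continue;
            for (int xx0 = 0; xx0 < X; ++xx0) {
              const int xx = xx0 + dx - pad;
              if (xx < 0 || xx >= X) continue;
              const long n = xx0 + (long)X * (y + (long)Y * z);
              const long dst = (long)C * (xx + (long)X * (yy + (long)Y * zz));
              const double* sp = col.colptr(n) + (long)C * o;
              double* dp = x.memptr() + dst;
              for (int c = 0; c < C; ++c) dp[c] += sp[c];
            }
          }
        }
      }
    }
  }
  return x;
}

// Symmetric Hausdorff distance between two voxel point sets in physical
// units; exact O(|A||B|) max-min sweep over anisotropic-spaced coordinates.
// [[Rcpp::export]]
double cpp_hausdorff(const arma::mat& A, const arma::mat& B,
                     const arma::vec& spacing) {
  const arma::rowvec s = spacing.t();
  arma::mat As = A.each_row() % s;
  arma::mat Bs = B.each_row() % s;
  double hAB = 0.0, hBA = 0.0;
  arma::vec minB(Bs.n_rows);
  minB.fill(arma::datum::inf);
  for (arma::uword i = 0; i < As.n_rows; ++i) {
    double best = arma::datum::inf;
    for (arma::uword j = 0; j < Bs.n_rows; ++j) {
      double d = 0.0;
      for (int d3 = 0; d3 < 3; ++d3) {
        const double t = As(i, d3) - Bs(j, d3);
        d += t * t;
      }
      if (d < best) best = d;
      if (d < minB(j)) minB(j) = d;
    }
    if (best > hAB) hAB = best;
  }
  hBA = minB.max();
  return std::sqrt(std::max(hAB, hBA));
}
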