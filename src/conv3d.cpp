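// 3D convolution kernels for the pocket leg of the network.
//
// Tensor layout: a single sample is a column vector of length C*X*Y*Z with
// index c + C*(x + X*(y + Y*z)) (channel fastest); a batch is the matrix
// (C*X*Y*Z) x N. Weights are (C_out x C_in*k^3) with column index
// ci + C_in*(kx + k*(ky + k*kz)). Convolutions are computed by im2col over
// the whole batch followed by a single GEMM: a batch output buffer of shape
// (C_out*nvox) x N is, column-major, identical to C_out x (nvox*N), so the
// GEMM writes straight into the result with no reshuffling.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// Fill the nvox-column block of `cols` for one sample.
static void im2col(const double* x, int C, int X, int Y, int Z,
                   int k, int stride, int pad, double* colblock,
                   int colstride) {
  const int Xo = out_size(X, k, stride, pad);
  const int Yo = out_size(Y, k, stride, pad);
  const int Zo = out_size(Z, k, stride, pad);
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const int v = ox + Xo * (oy + Yo * oz);
        double* col = colblock + (size_t)v * colstride;
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= X) continue;
              const double* src = x + C * (ix + X * (iy + Y * iz));
              double* dst = col + C * (kx + k * (ky + k * kz));
              std::copy(src, src + C, dst);
            }
          }
        }
      }
    }
  }
}

// Scatter-add one sample's column block back into its gradient column.
static void col2im(const double* colblock, int colstride, int C, int X,
                   int Y, int Z, int k, int stride, int pad, double* dx) {
  const int Xo = out_size(X, k, stride, pad);
  const int Yo = out_size(Y, k, stride, pad);
  const int Zo = out_size(Z, k, stride, pad);
  for (int oz = 0; oz < Zo; ++oz) {
    for (int oy = 0; oy < Yo; ++oy) {
      for (int ox = 0; ox < Xo; ++ox) {
        const int v = ox + Xo * (oy + Yo * oz);
        const double* col = colblock + (size_t)v * colstride;
        for (int kz = 0; kz < k; ++kz) {
          const int iz = oz * stride - pad + kz;
          if (iz < 0 || iz >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              const int ix = ox * stride - pad + kx;
              if (ix < 0 || ix >= X) continue;
              double* dst = dx + C * (ix + X * (iy + Y * iz));
              const double* src = col + C * (kx + k * (ky + k * kz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
    }
  }
}

// Persistent batch workspaces: reused across calls to avoid repeated
// multi-hundred-MB allocations in the training loop.
static std::vector<double>& workspace(int which, size_t need) {
  static std::vector<double> buf[2];
  if (buf[which].size() < need) buf[which].resize(need);
  return buf[which];
}

// [[Rcpp::export]]
NumericMatrix conv3d_fwd(NumericMatrix X, IntegerVector in_dim,
                         NumericMatrix W, NumericVector b,
                         int k, int stride, int pad) {
  const int C = in_dim[0], Xd = in_dim[1], Yd = in_dim[2], Zd = in_dim[3];
  const int N = X.ncol();
  const int Cout = W.nrow();
  const int Xo = out_size(Xd, k, stride, pad);
  const int Yo = out_size(Yd, k, stride, pad);
  const int Zo = out_size(Zd, k, stride, pad);
  const int nvox = Xo * Yo * Zo;
  const int ck3 = C * k * k * k;

  const size_t ncols = (size_t)ck3 * nvox * N;
  std::vector<double>& ws = workspace(0, ncols);
  std::memset(ws.data(), 0, ncols * sizeof(double));
  arma::mat cols(ws.data(), ck3, (size_t)nvox * N, false, true);
  for (int n = 0; n < N; ++n)
    im2col(&X(0, n), C, Xd, Yd, Zd, k, stride, pad,
           cols.colptr((size_t)n * nvox), ck3);

  NumericMatrix out(Cout * nvox, N);
  const arma::mat Wv(const_cast<double*>(&W(0, 0)), Cout, ck3, false, true);
  arma::mat outv(&out(0, 0), Cout, (size_t)nvox * N, false, true);
  outv = Wv * cols;
  const arma::vec bv(const_cast<double*>(&b[0]), Cout, false, true);
  outv.each_col() += bv;
  return out;
}

// dY must already include any activation mask. Returns dX, dW, db; with
// need_dx = false (first layer) the input gradient is skipped.
// [[Rcpp::export]]
List conv3d_bwd(NumericMatrix X, IntegerVector in_dim,
                NumericMatrix W, NumericMatrix dY,
                int k, int stride, int pad, bool need_dx = true) {
  const int C = in_dim[0], Xd = in_dim[1], Yd = in_dim[2], Zd = in_dim[3];
  const int N = X.ncol();
  const int Cout = W.nrow();
  const int Xo = out_size(Xd, k, stride, pad);
  const int Yo = out_size(Yd, k, stride, pad);
  const int Zo = out_size(Zd, k, stride, pad);
  const int nvox = Xo * Yo * Zo;
  const int ck3 = C * k * k * k;

  const size_t ncols = (size_t)ck3 * nvox * N;
  std::vector<double>& ws = workspace(0, ncols);
  std::memset(ws.data(), 0, ncols * sizeof(double));
  arma::mat cols(ws.data(), ck3, (size_t)nvox * N, false, true);
  for (int n = 0; n < N; ++n)
    im2col(&X(0, n), C, Xd, Yd, Zd, k, stride, pad,
           cols.colptr((size_t)n * nvox), ck3);

  const arma::mat Wv(const_cast<double*>(&W(0, 0)), Cout, ck3, false, true);
  const arma::mat dYv(const_cast<double*>(&dY(0, 0)), Cout,
                      (size_t)nvox * N, false, true);

  NumericMatrix dW(Cout, ck3);
  arma::mat dWv(&dW(0, 0), Cout, ck3, false, true);
  dWv = dYv * cols.t();
  NumericVector db(Cout);
  arma::vec dbv(&db[0], Cout, false, true);
  dbv = arma::sum(dYv, 1);

  NumericMatrix dX(need_dx ? X.nrow() : 1, need_dx ? N : 1);
  if (need_dx) {
    std::vector<double>& ws2 = workspace(1, ncols);
    arma::mat dcols(ws2.data(), ck3, (size_t)nvox * N, false, true);
    dcols = Wv.t() * dYv;
    std::fill(dX.begin(), dX.end(), 0.0);
    for (int n = 0; n < N; ++n)
      col2im(dcols.colptr((size_t)n * nvox), ck3, C, Xd, Yd, Zd, k,
             stride, pad, &dX(0, n));
  }
  return List::create(Named("dX") = dX, Named("dW") = dW,
                      Named("db") = db);
}

// In-place Adam update of one parameter tensor: p, m and v are modified
// directly (they are owned exclusively by the training loop).
// [[Rcpp::export]]
void adam_update(NumericVector p, NumericVector g, NumericVector m,
                 NumericVector v, double lr, double beta1, double beta2,
                 double eps, int t) {
  const R_xlen_t n = p.size();
  const double c1 = 1.0 - std::pow(beta1, t);
  const double c2 = 1.0 - std::pow(beta2, t);
  for (R_xlen_t i = 0; i < n; ++i) {
    m[i] = beta1 * m[i] + (1.0 - beta1) * g[i];
    v[i] = beta2 * v[i] + (1.0 - beta2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}
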