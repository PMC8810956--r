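// Dense kernels for the 3D CNN: same-padded 3x3x3 convolution via
// im2col + GEMM, and 2x2x2 max pooling. Tensors are passed as matrices
// with one column per sample; within a column the layout is the R array
// layout (x fastest, then y, z, channel):
//   index = x + nx*(y + ny*(z + nz*c)),  all 0-based.
// Convolution weights W are (c_out) x (c_in*27) with column
//   q = c_in_index*27 + (kz+1)*9 + (ky+1)*3 + (kx+1).
// The im2col buffer is kept transposed (P x c_in*27) so that the fill and
// scatter loops write/read contiguously along the voxel axis.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col_sample_t(const double* x, int nx, int ny, int nz, int nc,
                            arma::mat& colT) {
  const int P = nx * ny * nz;
  for (int c = 0; c < nc; ++c) {
    const double* xc = x + (size_t)c * P;
    for (int kz = -1; kz <= 1; ++kz)
      for (int ky = -1; ky <= 1; ++ky)
        for (int kx = -1; kx <= 1; ++kx) {
          const int q = c * 27 + (kz + 1) * 9 + (ky + 1) * 3 + (kx + 1);
          double* dst = colT.colptr(q);
          for (int z = 0; z < nz; ++z) {
            const int zz = z + kz;
            for (int y = 0; y < ny; ++y) {
              const int yy = y + ky;
              double* drow = dst + nx * (y + (size_t)ny * z);
              if (zz < 0 || zz >= nz || yy < 0 || yy >= ny) {
                std::fill(drow, drow + nx, 0.0);
                continue;
              }
              const double* srow = xc + nx * (yy + (size_t)ny * zz);
              // x-shifted copy with zero fill at the clipped ends
              int x0 = std::max(0, -kx), x1 = std::min(nx, nx - kx);
              if (kx > 0) drow[nx - 1] = 0.0;
              if (kx < 0) drow[0] = 0.0;
              for (int xi = x0; xi < x1; ++xi) drow[xi] = srow[xi + kx];
            }
          }
        }
  }
}

// [[Rcpp::export]]
arma::mat conv3d_fwd(const arma::mat& X, IntegerVector dims,
                     const arma::mat& W, const arma::vec& bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int B = X.n_cols;
  const int P = nx * ny * nz;
  const int cout_n = W.n_rows;
  if ((int)X.n_rows != P * nc) stop("conv3d_fwd: input size mismatch");
  if ((int)W.n_cols != nc * 27) stop("conv3d_fwd: weight size mismatch");
  arma::mat out(P * cout_n, B);
  arma::mat colT(P, nc * 27);
  arma::mat Wt = W.t();
  for (int b = 0; b < B; ++b) {
    im2col_sample_t(X.colptr(b), nx, ny, nz, nc, colT);
    arma::mat Yt = colT * Wt;  // P x cout
    double* o = out.colptr(b);
    for (int co = 0; co < cout_n; ++co) {
      const double* yc = Yt.colptr(co);
      const double bb = bias(co);
      double* oc = o + (size_t)P * co;
      for (int p = 0; p < P; ++p) oc[p] = yc[p] + bb;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd(const arma::mat& X, IntegerVector dims, const arma::mat& W,
                const arma::mat& dY, bool need_dx = true) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  const int B = X.n_cols;
  const int P = nx * ny * nz;
  const int cout_n = W.n_rows;
  arma::mat dWt(W.n_cols, W.n_rows, arma::fill::zeros);  // (nc*27) x cout
  arma::vec db(cout_n, arma::fill::zeros);
  arma::mat dX(X.n_rows, B, arma::fill::zeros);
  arma::mat colT(P, nc * 27);
  arma::mat dYt(P, cout_n);
  for (int b = 0; b < B; ++b) {
    const double* dy = dY.colptr(b);
    for (int co = 0; co < cout_n; ++co) {
      std::copy(dy + (size_t)P * co, dy + (size_t)P * (co + 1),
                dYt.colptr(co));
      db(co) += arma::accu(dYt.col(co));
    }
    im2col_sample_t(X.colptr(b), nx, ny, nz, nc, colT);
    dWt += colT.t() * dYt;
    if (!need_dx) continue;
    arma::mat dcolT = dYt * W;  // P x (nc*27), scatter back (col2im)
    double* dx = dX.colptr(b);
    for (int c = 0; c < nc; ++c) {
      double* dxc = dx + (size_t)c * P;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int q = c * 27 + (kz + 1) * 9 + (ky + 1) * 3 + (kx + 1);
            const double* src = dcolT.colptr(q);
            for (int z = 0; z < nz; ++z) {
              const int zz = z + kz;
              if (zz < 0 || zz >= nz) continue;
              for (int y = 0; y < ny; ++y) {
                const int yy = y + ky;
                if (yy < 0 || yy >= ny) continue;
                const double* srow = src + nx * (y + (size_t)ny * z);
                double* drow = dxc + nx * (yy + (size_t)ny * zz);
                int x0 = std::max(0, -kx), x1 = std::min(nx, nx - kx);
                for (int xi = x0; xi < x1; ++xi) drow[xi + kx] += srow[xi];
              }
            }
          }
    }
  }
  return List::create(Named("dX") = dX, Named("dW") = dWt.t(),
                      Named("db") = db);
}

// [[Rcpp::export]]
List maxpool3d_fwd(const arma::mat& X, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nc = dims[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool3d: odd spatial dimension");
  const int B = X.n_cols;
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int OP = ox * oy * oz;
  arma::mat out(OP * nc, B);
  IntegerMatrix argmax(OP * nc, B);
  for (int b = 0; b < B; ++b) {
    const double* x = X.colptr(b);
    double* o = out.colptr(b);
    for (int c = 0; c < nc; ++c) {
      const size_t cin = (size_t)c * nx * ny * nz;
      const size_t coff = (size_t)c * OP;
      for (int z = 0; z < oz; ++z)
        for (int y = 0; y < oy; ++y)
          for (int xi = 0; xi < ox; ++xi) {
            double best = -1e300;
            size_t bestidx = 0;
            for (int dz = 0; dz < 2; ++dz)
              for (int dy = 0; dy < 2; ++dy)
                for (int dx = 0; dx < 2; ++dx) {
                  const size_t ii = cin + (2 * xi + dx) +
                      (size_t)nx * ((2 * y + dy) + (size_t)ny * (2 * z + dz));
                  if (x[ii] > best) { best = x[ii]; bestidx = ii; }
                }
            const size_t oo = coff + xi + (size_t)ox * (y + (size_t)oy * z);
            o[oo] = best;
            argmax(oo, b) = (int)bestidx;
          }
    }
  }
  return List::create(Named("out") = out, Named("argmax") = argmax);
}

// [[Rcpp::export]]
arma::mat maxpool3d_bwd(const arma::mat& dY, IntegerMatrix argmax, int n_in) {
  const int B = dY.n_cols;
  arma::mat dX(n_in, B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    double* dx = dX.colptr(b);
    const double* dy = dY.colptr(b);
    for (int i = 0; i < (int)dY.n_rows; ++i) dx[argmax(i, b)] += dy[i];
  }
  return dX;
}
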