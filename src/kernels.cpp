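// Compiled numerical kernels: 3D convolution (im2col + GEMM) with its
// adjoint for backpropagation, brute-force k-nearest-neighbour labelling,
// and a separable 3D filter used by the SSIM metric.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Symmetric (reflect-with-repeat) boundary index: valid for |overhang| <= n.
static inline int reflect_idx(int i, int n) {
  if (i < 0) return -i - 1;
  if (i >= n) return 2 * n - i - 1;
  return i;
}

// Gather a z-slab of the symmetric-padded im2col matrix.
// x layout: (nx, ny, nz, cin) column-major for one batch element.
// col: rows = nx*ny*(z1-z0) voxels (x fastest), cols = k^3*cin with
// column index j = dx + k*(dy + k*dz) + k^3*c (matches the column-major
// flattening of a weight array dim (k,k,k,cin,cout)).
static void gather_chunk(const double* xp, arma::mat& col,
                         int nx, int ny, int nz, int cin,
                         int k, int z0, int z1) {
  const int h = k / 2, kk = k * k * k;
  const arma::uword rows = (arma::uword)nx * ny * (z1 - z0);
  col.set_size(rows, (arma::uword)kk * cin);
  for (int c = 0; c < cin; ++c) {
    const double* xc = xp + (size_t)c * nx * ny * nz;
    for (int dz = 0; dz < k; ++dz) {
      const int oz = dz - h;
      for (int dy = 0; dy < k; ++dy) {
        const int oy = dy - h;
        for (int dx = 0; dx < k; ++dx) {
          const int ox = dx - h;
          double* cp = col.colptr(dx + k * (dy + k * dz) + kk * c);
          for (int z = z0; z < z1; ++z) {
            const int zi = reflect_idx(z + oz, nz);
            for (int y = 0; y < ny; ++y) {
              const int yi = reflect_idx(y + oy, ny);
              const int xlo = std::max(0, -ox), xhi = std::min(nx, nx - ox);
              const double* src = xc + ((size_t)zi * ny + yi) * nx;
              double* dst = cp + ((size_t)(z - z0) * ny + y) * nx;
              for (int xx = 0; xx < xlo; ++xx)
                dst[xx] = src[reflect_idx(xx + ox, nx)];
              for (int xx = xlo; xx < xhi; ++xx) dst[xx] = src[xx + ox];
              for (int xx = xhi; xx < nx; ++xx)
                dst[xx] = src[reflect_idx(xx + ox, nx)];
            }
          }
        }
      }
    }
  }
}

// Adjoint of gather_chunk: scatter-add col gradients back into dx.
static void scatter_chunk(double* dxp, const arma::mat& dcol,
                          int nx, int ny, int nz, int cin,
                          int k, int z0, int z1) {
  const int h = k / 2, kk = k * k * k;
  for (int c = 0; c < cin; ++c) {
    double* xc = dxp + (size_t)c * nx * ny * nz;
    for (int dz = 0; dz < k; ++dz) {
      const int oz = dz - h;
      for (int dy = 0; dy < k; ++dy) {
        const int oy = dy - h;
        for (int dx = 0; dx < k; ++dx) {
          const int ox = dx - h;
          const double* cp = dcol.colptr(dx + k * (dy + k * dz) + kk * c);
          for (int z = z0; z < z1; ++z) {
            const int zi = reflect_idx(z + oz, nz);
            for (int y = 0; y < ny; ++y) {
              const int yi = reflect_idx(y + oy, ny);
              const int xlo = std::max(0, -ox), xhi = std::min(nx, nx - ox);
              double* dst = xc + ((size_t)zi * ny + yi) * nx;
              const double* src = cp + ((size_t)(z - z0) * ny + y) * nx;
              for (int xx = 0; xx < xlo; ++xx)
                dst[reflect_idx(xx + ox, nx)] += src[xx];
              for (int xx = xlo; xx < xhi; ++xx) dst[xx + ox] += src[xx];
              for (int xx = xhi; xx < nx; ++xx)
                dst[reflect_idx(xx + ox, nx)] += src[xx];
            }
          }
        }
      }
    }
  }
}

static int slab_chunk(int nx, int ny, int nz, int cin, int k) {
  double per_slice = (double)k * k * k * cin * nx * ny;
  int chunk = (int)std::max(1.0, 2.5e7 / per_slice);
  return std::min(chunk, nz);
}

// 'same' (zero-padded) 3D convolution, x: (nx,ny,nz,cin,nb),
// w: (k^3*cin, cout), b: length cout. Returns (nx,ny,nz,cout,nb).
// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, NumericMatrix w,
                             NumericVector b, int k) {
  IntegerVector d = x.attr("dim");
  if (d.size() < 4) stop("input must have dim (nx,ny,nz,cin[,nb])");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int nb = d.size() > 4 ? d[4] : 1;
  const int kk = k * k * k, cout = w.ncol();
  if (w.nrow() != kk * cin) stop("weight/input channel mismatch");
  if ((int)b.size() != cout) stop("bias length mismatch");
  const size_t V = (size_t)nx * ny * nz;
  NumericVector out(V * cout * nb);
  const arma::mat W(w.begin(), (arma::uword)kk * cin, cout, false);
  const arma::rowvec B(b.begin(), cout);
  const int chunk = slab_chunk(nx, ny, nz, cin, k);
  arma::mat col;
  for (int ib = 0; ib < nb; ++ib) {
    const double* xp = x.begin() + (size_t)ib * V * cin;
    double* op = out.begin() + (size_t)ib * V * cout;
    for (int z0 = 0; z0 < nz; z0 += chunk) {
      const int z1 = std::min(nz, z0 + chunk);
      gather_chunk(xp, col, nx, ny, nz, cin, k, z0, z1);
      arma::mat Y = col * W;
      Y.each_row() += B;
      const size_t rows = (size_t)nx * ny * (z1 - z0);
      for (int co = 0; co < cout; ++co)
        std::memcpy(op + (size_t)co * V + (size_t)z0 * nx * ny,
                    Y.colptr(co), sizeof(double) * rows);
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout, nb);
  return out;
}

// Gradients of conv3d_fwd_cpp. dy: (nx,ny,nz,cout,nb).
// Returns list(dw (k^3*cin x cout), db (cout), dx (same dim as x)).
// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, NumericMatrix w, NumericVector dy,
                    int k) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int nb = d.size() > 4 ? d[4] : 1;
  const int kk = k * k * k, cout = w.ncol();
  const size_t V = (size_t)nx * ny * nz;
  const arma::mat W(w.begin(), (arma::uword)kk * cin, cout, false);
  arma::mat dW((arma::uword)kk * cin, cout, arma::fill::zeros);
  arma::rowvec dB(cout, arma::fill::zeros);
  NumericVector dxv(x.size());
  const int chunk = slab_chunk(nx, ny, nz, cin, k);
  arma::mat col, dY;
  for (int ib = 0; ib < nb; ++ib) {
    const double* xp = x.begin() + (size_t)ib * V * cin;
    const double* gp = dy.begin() + (size_t)ib * V * cout;
    double* dxp = dxv.begin() + (size_t)ib * V * cin;
    for (int z0 = 0; z0 < nz; z0 += chunk) {
      const int z1 = std::min(nz, z0 + chunk);
      const size_t rows = (size_t)nx * ny * (z1 - z0);
      gather_chunk(xp, col, nx, ny, nz, cin, k, z0, z1);
      dY.set_size(rows, cout);
      for (int co = 0; co < cout; ++co)
        std::memcpy(dY.colptr(co), gp + (size_t)co * V + (size_t)z0 * nx * ny,
                    sizeof(double) * rows);
      dW += col.t() * dY;
      dB += arma::sum(dY, 0);
      arma::mat dcol = dY * W.t();
      scatter_chunk(dxp, dcol, nx, ny, nz, cin, k, z0, z1);
    }
  }
  NumericMatrix dwR(kk * cin, cout);
  std::memcpy(dwR.begin(), dW.memptr(), sizeof(double) * dW.n_elem);
  NumericVector dbR(cout);
  std::memcpy(dbR.begin(), dB.memptr(), sizeof(double) * cout);
  dxv.attr("dim") = d;
  return List::create(_["dw"] = dwR, _["db"] = dbR, _["dx"] = dxv);
}

// Majority label of the k nearest points (Euclidean) for each query row.
// TRUE where the majority of the k nearest reference points are fluid.
// [[Rcpp::export]]
LogicalVector knn_label_cpp(NumericMatrix query, NumericMatrix fluid,
                            NumericMatrix wall, int k) {
  const int nq = query.nrow(), nf = fluid.nrow(), nw = wall.nrow();
  const int np = nf + nw;
  if (k > np) stop("k exceeds the number of reference points");
  LogicalVector out(nq);
  std::vector<std::pair<double, int> > d(np);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < nf; ++j) {
      const double a = fluid(j, 0) - qx, b = fluid(j, 1) - qy,
                   c = fluid(j, 2) - qz;
      d[j] = std::make_pair(a * a + b * b + c * c, 1);
    }
    for (int j = 0; j < nw; ++j) {
      const double a = wall(j, 0) - qx, b = wall(j, 1) - qy,
                   c = wall(j, 2) - qz;
      d[nf + j] = std::make_pair(a * a + b * b + c * c, 0);
    }
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    int votes = 0;
    for (int j = 0; j < k; ++j) votes += d[j].second;
    out[i] = 2 * votes > k;
  }
  return out;
}

// Separable zero-padded filtering of a 3D array with a 1D kernel applied
// along each axis in turn (used for Gaussian-windowed SSIM statistics).
// [[Rcpp::export]]
NumericVector sep_filter3_cpp(NumericVector x, NumericVector kern) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  const int kl = kern.size(), h = kl / 2;
  const size_t V = (size_t)nx * ny * nz;
  std::vector<double> a(x.begin(), x.end()), b(V, 0.0);
  // axis x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const double* src = a.data() + ((size_t)z * ny + y) * nx;
      double* dst = b.data() + ((size_t)z * ny + y) * nx;
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        const int tlo = std::max(0, h - i), thi = std::min(kl, nx + h - i);
        for (int t = tlo; t < thi; ++t) s += kern[t] * src[i + t - h];
        dst[i] = s;
      }
    }
  std::fill(a.begin(), a.end(), 0.0);
  // axis y
  for (int z = 0; z < nz; ++z)
    for (int i = 0; i < nx; ++i) {
      const double* src = b.data() + (size_t)z * ny * nx + i;
      double* dst = a.data() + (size_t)z * ny * nx + i;
      for (int y = 0; y < ny; ++y) {
        double s = 0.0;
        const int tlo = std::max(0, h - y), thi = std::min(kl, ny + h - y);
        for (int t = tlo; t < thi; ++t) s += kern[t] * src[(size_t)(y + t - h) * nx];
        dst[(size_t)y * nx] = s;
      }
    }
  std::fill(b.begin(), b.end(), 0.0);
  // axis z
  const size_t plane = (size_t)nx * ny;
  for (int y = 0; y < ny; ++y)
    for (int i = 0; i < nx; ++i) {
      const double* src = a.data() + (size_t)y * nx + i;
      double* dst = b.data() + (size_t)y * nx + i;
      for (int z = 0; z < nz; ++z) {
        double s = 0.0;
        const int tlo = std::max(0, h - z), thi = std::min(kl, nz + h - z);
        for (int t = tlo; t < thi; ++t) s += kern[t] * src[(size_t)(z + t - h) * plane];
        dst[(size_t)z * plane] = s;
      }
    }
  NumericVector out(b.begin(), b.end());
  out.attr("dim") = d;
  return out;
}
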