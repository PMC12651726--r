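#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3x3 same-padded convolution over a (nx,ny,nz,cin) tensor
// stored x-fastest. Column k = c + cin*(dx + 3*(dy + 3*dz)), dx,dy,dz in 0..2.
static void build_col(const double* x, const int nx, const int ny,
                      const int nz, const int cin, arma::mat& col) {
  const size_t nvox = (size_t)nx * ny * nz;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + nvox * c;
    for (int dz = 0; dz < 3; ++dz)
    for (int dy = 0; dy < 3; ++dy)
    for (int dx = 0; dx < 3; ++dx) {
      const int k = c + cin * (dx + 3 * (dy + 3 * dz));
      double* ck = col.colptr(k);
      const int ox = dx - 1, oy = dy - 1, oz = dz - 1;
      for (int iz = 0; iz < nz; ++iz) {
        const int sz = iz + oz;
        for (int iy = 0; iy < ny; ++iy) {
          const int sy = iy + oy;
          double* dst = ck + (size_t)nx * (iy + (size_t)ny * iz);
          if (sz < 0 || sz >= nz || sy < 0 || sy >= ny) {
            std::fill(dst, dst + nx, 0.0);
            continue;
          }
          const double* src = xc + (size_t)nx * (sy + (size_t)ny * sz);
          const int lo = std::max(0, -ox), hi = std::min(nx, nx - ox);
          if (lo > 0) std::fill(dst, dst + lo, 0.0);
          std::copy(src + lo + ox, src + hi + ox, dst + lo);
          if (hi < nx) std::fill(dst + hi, dst + nx, 0.0);
        }
      }
    }
  }
}

// scatter-add of a column gradient back onto the input tensor (adjoint of
// build_col)
static void scatter_col(const arma::mat& dcol, const int nx, const int ny,
                        const int nz, const int cin, double* dx_out) {
  const size_t nvox = (size_t)nx * ny * nz;
  std::fill(dx_out, dx_out + nvox * cin, 0.0);
  for (int c = 0; c < cin; ++c) {
    double* xc = dx_out + nvox * c;
    for (int dz = 0; dz < 3; ++dz)
    for (int dy = 0; dy < 3; ++dy)
    for (int dxo = 0; dxo < 3; ++dxo) {
      const int k = c + cin * (dxo + 3 * (dy + 3 * dz));
      const double* ck = dcol.colptr(k);
      const int ox = dxo - 1, oy = dy - 1, oz = dz - 1;
      for (int iz = 0; iz < nz; ++iz) {
        const int sz = iz + oz;
        if (sz < 0 || sz >= nz) continue;
        for (int iy = 0; iy < ny; ++iy) {
          const int sy = iy + oy;
          if (sy < 0 || sy >= ny) continue;
          const double* src = ck + (size_t)nx * (iy + (size_t)ny * iz);
          double* dst = xc + (size_t)nx * (sy + (size_t)ny * sz);
          const int lo = std::max(0, -ox), hi = std::min(nx, nx - ox);
          for (int ix = lo; ix < hi; ++ix) dst[ix + ox] += src[ix];
        }
      }
    }
  }
}

// Forward 3x3x3 same convolution: returns (nx,ny,nz,cout) tensor.
// W is a (27*cin) x cout matrix in build_col's column order; b length cout.
// [[Rcpp::export]]
NumericVector conv3d_forward_cpp(const NumericVector& x,
                                 const IntegerVector& xdim,
                                 const NumericMatrix& W,
                                 const NumericVector& b) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const size_t nvox = (size_t)nx * ny * nz;
  const int cout = W.ncol();
  arma::mat col(nvox, 27 * cin);
  build_col(x.begin(), nx, ny, nz, cin, col);
  const arma::mat Wm(const_cast<double*>(W.begin()), 27 * cin, cout, false);
  arma::mat out = col * Wm;
  for (int c = 0; c < cout; ++c) out.col(c) += b[c];
  NumericVector res(nvox * cout);
  std::copy(out.begin(), out.end(), res.begin());
  res.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return res;
}

// Backward pass: gradients with respect to input, weights and bias.
// [[Rcpp::export]]
List conv3d_backward_cpp(const NumericVector& x,
                         const IntegerVector& xdim,
                         const NumericMatrix& W,
                         const NumericVector& dy) {
  const int nx = xdim[0], ny = xdim[1], nz = xdim[2], cin = xdim[3];
  const size_t nvox = (size_t)nx * ny * nz;
  const int cout = W.ncol();
  arma::mat col(nvox, 27 * cin);
  build_col(x.begin(), nx, ny, nz, cin, col);
  const arma::mat Wm(const_cast<double*>(W.begin()), 27 * cin, cout, false);
  const arma::mat dym(const_cast<double*>(dy.begin()), nvox, cout, false);
  arma::mat dW = col.t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  arma::mat dcol = dym * Wm.t();
  NumericVector dx(nvox * cin);
  scatter_col(dcol, nx, ny, nz, cin, dx.begin());
  dx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  NumericMatrix dWout(27 * cin, cout);
  std::copy(dW.begin(), dW.end(), dWout.begin());
  return List::create(_["dx"] = dx, _["dW"] = dWout,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
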