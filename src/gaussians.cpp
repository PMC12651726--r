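#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Symmetric inverse covariance packed as a11,a22,a33,a12,a13,a23.
static inline double quadform(const double* A, double dx, double dy, double dz) {
  return A[0]*dx*dx + A[1]*dy*dy + A[2]*dz*dz
       + 2.0*(A[3]*dx*dy + A[4]*dx*dz + A[5]*dy*dz);
}

// Additive compositing of intensity-valued anisotropic Gaussians onto a
// voxel grid with centres at 1..dim per axis. Each point is evaluated
// inside its own bounding cube of half-width radius[p] (voxels).
// [[Rcpp::export]]
NumericVector render_gaussians_cpp(const NumericMatrix& mu,
                                   const NumericMatrix& Ainv,
                                   const NumericVector& intensity,
                                   const IntegerVector& dims,
                                   const NumericVector& radius) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nx * ny * nz);
  const int N = mu.nrow();
  for (int p = 0; p < N; ++p) {
    double A[6]; for (int k = 0; k < 6; ++k) A[k] = Ainv(p, k);
    const double i0 = intensity[p], r = radius[p];
    const double mx = mu(p,0), my = mu(p,1), mz = mu(p,2);
    const int x0 = std::max(0, (int)std::floor(mx - r) - 1);
    const int x1 = std::min(nx - 1, (int)std::ceil(mx + r) - 1);
    const int y0 = std::max(0, (int)std::floor(my - r) - 1);
    const int y1 = std::min(ny - 1, (int)std::ceil(my + r) - 1);
    const int z0 = std::max(0, (int)std::floor(mz - r) - 1);
    const int z1 = std::min(nz - 1, (int)std::ceil(mz + r) - 1);
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = (iz + 1) - mz;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = (iy + 1) - my;
        double* col = &out[(size_t)nx * (iy + (size_t)ny * iz)];
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = (ix + 1) - mx;
          col[ix] += i0 * std::exp(-0.5 * quadform(A, dx, dy, dz));
        }
      }
    }
  }
  return out;
}

// Loss and analytic gradients of loss(render(field), target) with respect
// to the per-point mean, packed inverse covariance, and intensity.
// loss_kind: 0 = mean squared error, 1 = mean absolute error.
// [[Rcpp::export]]
List render_loss_grad_cpp(const NumericMatrix& mu,
                          const NumericMatrix& Ainv,
                          const NumericVector& intensity,
                          const IntegerVector& dims,
                          const NumericVector& radius,
                          const NumericVector& target,
                          const int loss_kind) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  NumericVector V = render_gaussians_cpp(mu, Ainv, intensity, dims, radius);
  std::vector<double> dl(nvox);
  double loss = 0.0;
  for (size_t v = 0; v < nvox; ++v) {
    const double r = V[v] - target[v];
    if (loss_kind == 0) { loss += r * r; dl[v] = 2.0 * r / nvox; }
    else { loss += std::fabs(r); dl[v] = (r > 0 ? 1.0 : (r < 0 ? -1.0 : 0.0)) / nvox; }
  }
  loss /= nvox;

  const int N = mu.nrow();
  NumericMatrix gmu(N, 3), gA(N, 6);
  NumericVector gi(N);
  for (int p = 0; p < N; ++p) {
    double A[6]; for (int k = 0; k < 6; ++k) A[k] = Ainv(p, k);
    const double i0 = intensity[p], r = radius[p];
    const double mx = mu(p,0), my = mu(p,1), mz = mu(p,2);
    const int x0 = std::max(0, (int)std::floor(mx - r) - 1);
    const int x1 = std::min(nx - 1, (int)std::ceil(mx + r) - 1);
    const int y0 = std::max(0, (int)std::floor(my - r) - 1);
    const int y1 = std::min(ny - 1, (int)std::ceil(my + r) - 1);
    const int z0 = std::max(0, (int)std::floor(mz - r) - 1);
    const int z1 = std::min(nz - 1, (int)std::ceil(mz + r) - 1);
    double g0=0, g1=0, g2=0, ga0=0, ga1=0, ga2=0, ga3=0, ga4=0, ga5=0, gint=0;
    for (int iz = z0; iz <= z1; ++iz) {
      const double dz = (iz + 1) - mz;
      for (int iy = y0; iy <= y1; ++iy) {
        const double dy = (iy + 1) - my;
        const double* dcol = &dl[(size_t)nx * (iy + (size_t)ny * iz)];
        for (int ix = x0; ix <= x1; ++ix) {
          const double dx = (ix + 1) - mx;
          const double e = std::exp(-0.5 * quadform(A, dx, dy, dz));
          const double g = dcol[ix];
          if (g == 0.0) continue;
          const double ie = i0 * e * g;
          gint += g * e;
          // dV/dmu = i e * (A d)
          g0 += ie * (A[0]*dx + A[3]*dy + A[4]*dz);
          g1 += ie * (A[3]*dx + A[1]*dy + A[5]*dz);
          g2 += ie * (A[4]*dx + A[5]*dy + A[2]*dz);
          // dV/dA: diagonal -1/2 i e d_k^2, off-diagonal pair -i e d_j d_k
          ga0 += -0.5 * ie * dx * dx;
          ga1 += -0.5 * ie * dy * dy;
          ga2 += -0.5 * ie * dz * dz;
          ga3 += -ie * dx * dy;
          ga4 += -ie * dx * dz;
          ga5 += -ie * dy * dz;
        }
      }
    }
    gmu(p,0)=g0; gmu(p,1)=g1; gmu(p,2)=g2;
    gA(p,0)=ga0; gA(p,1)=ga1; gA(p,2)=ga2; gA(p,3)=ga3; gA(p,4)=ga4; gA(p,5)=ga5;
    gi[p] = gint;
  }
  return List::create(_["loss"] = loss, _["grad_mu"] = gmu,
                      _["grad_A"] = gA, _["grad_i"] = gi);
}
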