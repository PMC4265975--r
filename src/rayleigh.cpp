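#include <Rcpp.h>
#include <complex>
#include <cmath>

using namespace Rcpp;

// Rayleigh-Sommerfeld summation over discretized source patches.
//
// p(r_j) = C * sum_i u_i * exp(-(alpha + i k) d_ij) / d_ij * dS_i
//
// with d_ij = max(|r_j - s_i|, reg_i) (regularized by the patch radius so a
// field point coincident with a patch stays finite). The prefactor
// C = i rho c k / (2 pi) is applied by the R caller. All lengths in metres.
// [[Rcpp::export]]
ComplexVector rayleigh_sum_cpp(NumericMatrix points, NumericMatrix src,
                               NumericVector area, ComplexVector u,
                               double k, double alpha, NumericVector reg) {
  const int np = points.nrow();
  const int ns = src.nrow();
  ComplexVector out(np);
  const double *sx = &src(0, 0), *sy = &src(0, 1), *sz = &src(0, 2);
  for (int j = 0; j < np; ++j) {
    const double px = points(j, 0), py = points(j, 1), pz = points(j, 2);
    double acc_re = 0.0, acc_im = 0.0;
    for (int i = 0; i < ns; ++i) {
      const double dx = px - sx[i], dy = py - sy[i], dz = pz - sz[i];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < reg[i]) d = reg[i];
      const double amp = std::exp(-alpha * d) * area[i] / d;
      const double ph = -k * d;
      const double c = std::cos(ph), s = std::sin(ph);
      const double ur = u[i].r, ui = u[i].i;
      // (ur + i ui) * (c + i s) * amp
      acc_re += amp * (ur * c - ui * s);
      acc_im += amp * (ur * s + ui * c);
    }
    out[j].r = acc_re;
    out[j].i = acc_im;
  }
  return out;
}

// Far-field disc-element summation: each element contributes
//   u_e * A_e * D(theta) * exp(-(alpha + i k) d) / d
// where D = 2 J1(x)/x with x = k a sin(theta) is the baffled-disc
// directivity and theta the angle between the element normal and the
// direction to the field point. Valid for distances well beyond the
// element Rayleigh distance a^2/lambda (a few mm here vs the 120-mm focal
// length). J1 is evaluated through a dense lookup table for speed.
// [[Rcpp::export]]
ComplexVector element_farfield_cpp(NumericMatrix points, NumericMatrix centers,
                                   NumericMatrix normals, NumericVector area,
                                   ComplexVector u, double k, double alpha,
                                   double a_m) {
  const int np = points.nrow();
  const int ne = centers.nrow();
  const double ka = k * a_m;
  // directivity table over x in [0, xmax]
  const int NT = 4096;
  const double xmax = ka + 1e-9;
  std::vector<double> dir(NT + 1);
  dir[0] = 1.0;
  for (int i = 1; i <= NT; ++i) {
    const double x = xmax * i / NT;
#if defined(__GNUC__) && !defined(__clang__)
    const double j1 = std::cyl_bessel_j(1.0, x);
#else
    const double j1 = ::j1(x);
#endif
    dir[i] = 2.0 * j1 / x;
  }
  ComplexVector out(np);
  for (int j = 0; j < np; ++j) {
    const double px = points(j, 0), py = points(j, 1), pz = points(j, 2);
    double acc_re = 0.0, acc_im = 0.0;
    for (int e = 0; e < ne; ++e) {
      const double ur = u[e].r, ui = u[e].i;
      if (ur == 0.0 && ui == 0.0) continue;
      const double dx = px - centers(e, 0), dy = py - centers(e, 1),
                   dz = pz - centers(e, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d <= 0) continue;
      double ct = (dx * normals(e, 0) + dy * normals(e, 1) +
                   dz * normals(e, 2)) / d;
      if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
      const double st = std::sqrt(1.0 - ct * ct);
      const double x = ka * st;
      double D;
      const double fi = x / xmax * NT;
      const int i0 = (int)fi;
      if (i0 >= NT) D = dir[NT];
      else D = dir[i0] + (fi - i0) * (dir[i0 + 1] - dir[i0]);
      const double amp = std::exp(-alpha * d) * area[e] * D / d;
      const double ph = -k * d;
      const double c = std::cos(ph), s = std::sin(ph);
      acc_re += amp * (ur * c - ui * s);
      acc_im += amp * (ur * s + ui * c);
    }
    out[j].r = acc_re;
    out[j].i = acc_im;
  }
  return out;
}

// 3D Laplacian with Dirichlet (fixed bc value) or Neumann (zero-flux)
// boundaries; singleton axes contribute nothing.
// [[Rcpp::export]]
NumericVector laplacian3_cpp(NumericVector arr, IntegerVector dim,
                             NumericVector inv_h2, bool dirichlet,
                             double bc) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double ix = inv_h2[0], iy = inv_h2[1], iz = inv_h2[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *a = &arr[0];
  double *o = &out[0];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      const size_t base = nx * ((size_t)y + (size_t)ny * z);
      for (int x = 0; x < nx; ++x) {
        const size_t i = base + x;
        const double c = a[i];
        double lap = 0.0;
        if (nx > 1) {
          const double xm = (x > 0) ? a[i - 1] : (dirichlet ? bc : c);
          const double xp = (x < nx - 1) ? a[i + 1] : (dirichlet ? bc : c);
          lap += (xm + xp - 2.0 * c) * ix;
        }
        if (ny > 1) {
          const double ym = (y > 0) ? a[i - nx] : (dirichlet ? bc : c);
          const double yp = (y < ny - 1) ? a[i + nx] : (dirichlet ? bc : c);
          lap += (ym + yp - 2.0 * c) * iy;
        }
        if (nz > 1) {
          const size_t pz_ = (size_t)nx * ny;
          const double zm = (z > 0) ? a[i - pz_] : (dirichlet ? bc : c);
          const double zp = (z < nz - 1) ? a[i + pz_] : (dirichlet ? bc : c);
          lap += (zm + zp - 2.0 * c) * iz;
        }
        o[i] = lap;
      }
    }
  }
  return out;
}

// Trilinear interpolation of a 3D array at arbitrary points given in
// fractional (0-based) voxel coordinates. Out-of-bounds points return fill.
// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericVector arr, IntegerVector dim,
                            NumericMatrix idx, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int np = idx.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
      out[p] = fill;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2; if (x0 < 0) x0 = 0;
    if (y0 > ny - 2) y0 = ny - 2; if (y0 < 0) y0 = 0;
    if (z0 > nz - 2) z0 = nz - 2; if (z0 < 0) z0 = 0;
    // singleton dimensions: stay on the only plane
    const int dxs = (nx > 1) ? 1 : 0, dys = (ny > 1) ? 1 : 0,
              dzs = (nz > 1) ? 1 : 0;
    const double fx = dxs ? x - x0 : 0.0, fy = dys ? y - y0 : 0.0,
                 fz = dzs ? z - z0 : 0.0;
    const double *a = &arr[0];
    #define AT(i, j, l) a[(i) + nx * ((j) + (size_t)ny * (l))]
    const double c00 = AT(x0, y0, z0) * (1 - fx) + AT(x0 + dxs, y0, z0) * fx;
    const double c10 = AT(x0, y0 + dys, z0) * (1 - fx) + AT(x0 + dxs, y0 + dys, z0) * fx;
    const double c01 = AT(x0, y0, z0 + dzs) * (1 - fx) + AT(x0 + dxs, y0, z0 + dzs) * fx;
    const double c11 = AT(x0, y0 + dys, z0 + dzs) * (1 - fx) + AT(x0 + dxs, y0 + dys, z0 + dzs) * fx;
    #undef AT
    const double c0 = c00 * (1 - fy) + c10 * fy;
    const double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}
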