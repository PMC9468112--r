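#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Ray-driven cone-beam line integrals with trilinear sampling.
//
// The volume lives on a regular grid: voxel (i,j,k) (0-based) at
// origin + idx * spacing (world mm). A rigid pose applied to the volume is
// handled by inverse-transforming the rays: the caller passes the inverse
// pose (invR, invT) mapping world points into the untransformed volume
// frame. Only detector pixels inside the ROI (r0..r1, c0..c1, 0-based,
// inclusive) are computed; the returned matrix has the ROI's size.

static inline double trilinear(const double *v, int nx, int ny, int nz,
                               double x, double y, double z) {
  int ix = (int)std::floor(x), iy = (int)std::floor(y), iz = (int)std::floor(z);
  if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 || iz >= nz - 1) {
    // clamp-free: outside samples contribute zero (volume padded with air)
    if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
      return 0.0;
    ix = std::min(ix, nx - 2); iy = std::min(iy, ny - 2); iz = std::min(iz, nz - 2);
  }
  double fx = x - ix, fy = y - iy, fz = z - iz;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double *p = v + ix + iy * sy + iz * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sy + sz] * (1 - fx) + p[sy + sz + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericMatrix cpp_drr_project(NumericVector vol, IntegerVector dim,
                              NumericVector spacing, NumericVector origin,
                              NumericVector src, NumericVector detCenter,
                              NumericVector detRow, NumericVector detCol,
                              double pitch, IntegerVector detDim,
                              IntegerVector roi, NumericMatrix invR,
                              NumericVector invT, double step) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double *v = vol.begin();
  const int nr = detDim[0], nc = detDim[1];
  const int r0 = roi[0], r1 = roi[1], c0 = roi[2], c1 = roi[3];
  if (r0 < 0 || c0 < 0 || r1 >= nr || c1 >= nc || r1 < r0 || c1 < c0)
    stop("ROI outside the detector");
  NumericMatrix out(r1 - r0 + 1, c1 - c0 + 1);

  // source in volume frame
  double S[3];
  for (int a = 0; a < 3; ++a)
    S[a] = invR(a, 0) * src[0] + invR(a, 1) * src[1] + invR(a, 2) * src[2] + invT[a];
  // detector basis in volume frame
  double U[3], V[3], D[3];
  for (int a = 0; a < 3; ++a) {
    U[a] = invR(a, 0) * detRow[0] + invR(a, 1) * detRow[1] + invR(a, 2) * detRow[2];
    V[a] = invR(a, 0) * detCol[0] + invR(a, 1) * detCol[1] + invR(a, 2) * detCol[2];
    D[a] = invR(a, 0) * detCenter[0] + invR(a, 1) * detCenter[1] +
           invR(a, 2) * detCenter[2] + invT[a];
  }
  const double halfR = (nr - 1) / 2.0, halfC = (nc - 1) / 2.0;
  const double eps = 1e-12;

  for (int i = r0; i <= r1; ++i) {
    const double du = (i - halfR) * pitch;
    for (int j = c0; j <= c1; ++j) {
      const double dv = (j - halfC) * pitch;
      double P[3], d[3];
      double len = 0;
      for (int a = 0; a < 3; ++a) {
        P[a] = D[a] + du * U[a] + dv * V[a];
        d[a] = P[a] - S[a];
        len += d[a] * d[a];
      }
      len = std::sqrt(len);
      double tmin = 0.0, tmax = len;
      bool ok = true;
      for (int a = 0; a < 3 && ok; ++a) {
        const double o = (S[a] - origin[a]) / spacing[a];
        const double dd = d[a] / len / spacing[a];
        const double lim = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1.0;
        if (std::fabs(dd) < eps) {
          if (o < 0 || o > lim) ok = false;
        } else {
          double t0 = (0.0 - o) / dd, t1 = (lim - o) / dd;
          if (t0 > t1) std::swap(t0, t1);
          if (t0 > tmin) tmin = t0;
          if (t1 < tmax) tmax = t1;
        }
      }
      double acc = 0.0;
      if (ok && tmax > tmin) {
        const int nstep = (int)std::ceil((tmax - tmin) / step);
        const double h = (tmax - tmin) / nstep; // uniform substep <= step
        double x = (S[0] - origin[0]) / spacing[0];
        double y = (S[1] - origin[1]) / spacing[1];
        double z = (S[2] - origin[2]) / spacing[2];
        const double dx = d[0] / len / spacing[0];
        const double dy = d[1] / len / spacing[1];
        const double dz = d[2] / len / spacing[2];
        for (int k = 0; k < nstep; ++k) {
          const double t = tmin + (k + 0.5) * h;
          acc += trilinear(v, nx, ny, nz, x + t * dx, y + t * dy, z + t * dz);
        }
        acc *= h;
      }
      out(i - r0, j - c0) = acc;
    }
  }
  return out;
}

// Analytic line integrals through homogeneous spheres (skin markers):
// contribution 2 * mu * sqrt(r^2 - d^2) where d is the ray-center distance.
// [[Rcpp::export]]
NumericMatrix cpp_render_spheres(NumericMatrix centers, double radius,
                                 double mu, NumericVector src,
                                 NumericVector detCenter, NumericVector detRow,
                                 NumericVector detCol, double pitch,
                                 IntegerVector detDim, IntegerVector roi) {
  const int nr = detDim[0], nc = detDim[1];
  const int r0 = roi[0], r1 = roi[1], c0 = roi[2], c1 = roi[3];
  if (r0 < 0 || c0 < 0 || r1 >= nr || c1 >= nc)
    stop("ROI outside the detector");
  NumericMatrix out(r1 - r0 + 1, c1 - c0 + 1);
  const double halfR = (nr - 1) / 2.0, halfC = (nc - 1) / 2.0;
  const int m = centers.nrow();
  const double r2 = radius * radius;

  // marker positions relative to source; require markers in front of source
  std::vector<double> M(3 * m);
  double w[3];
  double sdd = 0;
  for (int a = 0; a < 3; ++a) {
    w[a] = detCenter[a] - src[a];
    sdd += w[a] * w[a];
  }
  sdd = std::sqrt(sdd);
  for (int a = 0; a < 3; ++a) w[a] /= sdd;
  for (int k = 0; k < m; ++k) {
    double depth = 0;
    for (int a = 0; a < 3; ++a) {
      M[3 * k + a] = centers(k, a) - src[a];
      depth += M[3 * k + a] * w[a];
    }
    if (depth <= radius)
      stop("marker at or behind the source plane");
  }

  for (int i = r0; i <= r1; ++i) {
    const double du = (i - halfR) * pitch;
    for (int j = c0; j <= c1; ++j) {
      const double dv = (j - halfC) * pitch;
      double d[3];
      double len = 0;
      for (int a = 0; a < 3; ++a) {
        d[a] = detCenter[a] + du * detRow[a] + dv * detCol[a] - src[a];
        len += d[a] * d[a];
      }
      len = std::sqrt(len);
      double acc = 0;
      for (int k = 0; k < m; ++k) {
        const double *c = &M[3 * k];
        double proj = (c[0] * d[0] + c[1] * d[1] + c[2] * d[2]) / len;
        if (proj <= 0) continue;
        double dist2 = c[0] * c[0] + c[1] * c[1] + c[2] * c[2] - proj * proj;
        if (dist2 < r2)
          acc += 2.0 * mu * std::sqrt(r2 - dist2);
      }
      out(i - r0, j - c0) = acc;
    }
  }
  return out;
}
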