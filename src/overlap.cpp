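#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exponential lookup table convention shared with the R side:
// lut[k] = exp(-12 + 0.002 * k), k = 0..6000.  Arguments below -12 evaluate
// to zero; arguments are never positive (Gaussian exponents are <= 0).
static inline double lut_exp(double x, const double* lut) {
  if (x < -12.0) return 0.0;
  if (x >= 0.0) return 1.0;
  int k = (int)std::lround((x + 12.0) * 500.0);
  if (k < 0) k = 0;
  if (k > 6000) k = 6000;
  return lut[k];
}

static inline double pair_term(double ai, double aj, double d2, double p2,
                               const double* lut) {
  double s = ai + aj;
  double pre = std::pow(M_PI / s, 1.5);
  return p2 * pre * lut_exp(-(ai * aj / s) * d2, lut);
}

// First-order Grant-Pickup overlap volume between two rigid atom sets.
// A, B: n x 3 coordinate matrices (heavy atoms only); aA, aB: Gaussian
// exponents per atom; p2 = amplitude^2.
// [[Rcpp::export]]
double cpp_overlap(NumericMatrix A, NumericVector aA, NumericMatrix B,
                   NumericVector aB, double p2, NumericVector lut) {
  const int nA = A.nrow(), nB = B.nrow();
  const double* L = lut.begin();
  double v = 0.0;
  for (int i = 0; i < nA; ++i) {
    const double xi = A(i, 0), yi = A(i, 1), zi = A(i, 2), ai = aA[i];
    for (int j = 0; j < nB; ++j) {
      const double dx = xi - B(j, 0), dy = yi - B(j, 1), dz = zi - B(j, 2);
      v += pair_term(ai, aB[j], dx * dx + dy * dy + dz * dz, p2, L);
    }
  }
  return v;
}

static inline void quat_rotate(const double* q, double x, double y, double z,
                               double* out) {
  // rotate (x,y,z) by unit quaternion q = (w, qx, qy, qz)
  const double w = q[0], qx = q[1], qy = q[2], qz = q[3];
  // t = 2 * q_vec x v
  double tx = 2.0 * (qy * z - qz * y);
  double ty = 2.0 * (qz * x - qx * z);
  double tz = 2.0 * (qx * y - qy * x);
  out[0] = x + w * tx + (qy * tz - qz * ty);
  out[1] = y + w * ty + (qz * tx - qx * tz);
  out[2] = z + w * tz + (qx * ty - qy * tx);
}

// Overlap of A with B transformed by (q, t): x_B' = R(q) x_B + t.
// [[Rcpp::export]]
double cpp_overlap_transformed(NumericMatrix A, NumericVector aA,
                               NumericMatrix B, NumericVector aB, double p2,
                               NumericVector lut, NumericVector q,
                               NumericVector t) {
  const int nA = A.nrow(), nB = B.nrow();
  const double* L = lut.begin();
  double v = 0.0, r[3];
  for (int j = 0; j < nB; ++j) {
    quat_rotate(q.begin(), B(j, 0), B(j, 1), B(j, 2), r);
    const double bx = r[0] + t[0], by = r[1] + t[1], bz = r[2] + t[2];
    const double aj = aB[j];
    for (int i = 0; i < nA; ++i) {
      const double dx = A(i, 0) - bx, dy = A(i, 1) - by, dz = A(i, 2) - bz;
      v += pair_term(aA[i], aj, dx * dx + dy * dy + dz * dz, p2, L);
    }
  }
  return v;
}

// Objective for the local shape optimizer: negative overlap at the transform
// q0 * dq(rotvec), t0 + dt, where par = (rotvec, dt).  Keeping the whole
// evaluation on the C++ side makes a Nelder-Mead iteration cheap.
// [[Rcpp::export]]
double cpp_neg_overlap_par(NumericVector par, NumericVector q0,
                           NumericVector t0, NumericMatrix A, NumericVector aA,
                           NumericMatrix B, NumericVector aB, double p2,
                           NumericVector lut) {
  double rx = par[0], ry = par[1], rz = par[2];
  double th = std::sqrt(rx * rx + ry * ry + rz * rz);
  double dq[4];
  if (th < 1e-12) {
    dq[0] = 1.0; dq[1] = 0.0; dq[2] = 0.0; dq[3] = 0.0;
  } else {
    double s = std::sin(0.5 * th) / th;
    dq[0] = std::cos(0.5 * th);
    dq[1] = rx * s; dq[2] = ry * s; dq[3] = rz * s;
  }
  // q = q0 * dq
  const double w1 = q0[0], x1 = q0[1], y1 = q0[2], z1 = q0[3];
  double q[4];
  q[0] = w1 * dq[0] - x1 * dq[1] - y1 * dq[2] - z1 * dq[3];
  q[1] = w1 * dq[1] + x1 * dq[0] + y1 * dq[3] - z1 * dq[2];
  q[2] = w1 * dq[2] - x1 * dq[3] + y1 * dq[0] + z1 * dq[1];
  q[3] = w1 * dq[3] + x1 * dq[2] - y1 * dq[1] + z1 * dq[0];
  NumericVector qv(4), tv(3);
  for (int k = 0; k < 4; ++k) qv[k] = q[k];
  tv[0] = t0[0] + par[3]; tv[1] = t0[1] + par[4]; tv[2] = t0[2] + par[5];
  return -cpp_overlap_transformed(A, aA, B, aB, p2, lut, qv, tv);
}

// Shape grid: overlap of a carbon probe atom centered at each lattice point
// with the owning conformer; atoms beyond `cutoff` of a point contribute 0.
// Values laid out with x fastest, then y, then z.
// [[Rcpp::export]]
NumericVector cpp_build_grid(NumericMatrix X, NumericVector alpha,
                             double probe_alpha, double p2, NumericVector lut,
                             NumericVector origin, IntegerVector dims,
                             double spacing, double cutoff) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], n = X.nrow();
  const double c2 = cutoff * cutoff;
  const double* L = lut.begin();
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t idx = 0;
  for (int kz = 0; kz < nz; ++kz) {
    const double z = origin[2] + kz * spacing;
    for (int ky = 0; ky < ny; ++ky) {
      const double y = origin[1] + ky * spacing;
      for (int kx = 0; kx < nx; ++kx, ++idx) {
        const double x = origin[0] + kx * spacing;
        double v = 0.0;
        for (int i = 0; i < n; ++i) {
          const double dx = x - X(i, 0), dy = y - X(i, 1), dz = z - X(i, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > c2) continue;
          v += pair_term(probe_alpha, alpha[i], d2, p2, L);
        }
        out[idx] = v;
      }
    }
  }
  return out;
}

// Sum of trilinearly interpolated grid values at transformed query positions,
// each scaled by `scale`; points outside the grid contribute 0.
// [[Rcpp::export]]
double cpp_grid_overlap(NumericVector values, NumericVector origin,
                        IntegerVector dims, double spacing, NumericMatrix P,
                        NumericVector scale, NumericVector q,
                        NumericVector t) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = P.nrow();
  double total = 0.0, r[3];
  for (int j = 0; j < m; ++j) {
    quat_rotate(q.begin(), P(j, 0), P(j, 1), P(j, 2), r);
    const double fx = (r[0] + t[0] - origin[0]) / spacing;
    const double fy = (r[1] + t[1] - origin[1]) / spacing;
    const double fz = (r[2] + t[2] - origin[2]) / spacing;
    const int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
              iz = (int)std::floor(fz);
    if (ix < 0 || iy < 0 || iz < 0 || ix >= nx - 1 || iy >= ny - 1 ||
        iz >= nz - 1)
      continue;
    const double ux = fx - ix, uy = fy - iy, uz = fz - iz;
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    const R_xlen_t base = ix + (R_xlen_t)iy * nx + (R_xlen_t)iz * sxy;
    const double* v = values.begin();
    double c00 = v[base] * (1 - ux) + v[base + 1] * ux;
    double c10 = v[base + nx] * (1 - ux) + v[base + nx + 1] * ux;
    double c01 = v[base + sxy] * (1 - ux) + v[base + sxy + 1] * ux;
    double c11 = v[base + sxy + nx] * (1 - ux) + v[base + sxy + nx + 1] * ux;
    double c0 = c00 * (1 - uy) + c10 * uy;
    double c1 = c01 * (1 - uy) + c11 * uy;
    total += scale[j] * (c0 * (1 - uz) + c1 * uz);
  }
  return total;
}
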