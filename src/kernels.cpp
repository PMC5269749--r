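#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a volume at fractional voxel coordinates (0-based).
// Values are interpolated between voxel centres; inside the half-voxel
// boundary shell [-0.5, n-0.5] coordinates clamp to the edge value (voxels
// have spatial extent), outside it the field is zero.
static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < -0.5 || y < -0.5 || z < -0.5 ||
      x > nx - 0.5 || y > ny - 0.5 || z > nz - 0.5) return 0.0;
  if (x < 0.0) x = 0.0; if (x > nx - 1.0) x = nx - 1.0;
  if (y < 0.0) y = 0.0; if (y > ny - 1.0) y = ny - 1.0;
  if (z < 0.0) z = 0.0; if (z > nz - 1.0) z = nz - 1.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const long sx = 1, sy = nx, sz = (long)nx * ny;
  const double* p = v + i0 * sx + j0 * sy + k0 * sz;
  double c00 = p[0]      * (1 - fx) + p[sx]           * fx;
  double c10 = p[sy]     * (1 - fx) + p[sx + sy]      * fx;
  double c01 = p[sz]     * (1 - fx) + p[sx + sz]      * fx;
  double c11 = p[sy + sz]* (1 - fx) + p[sx + sy + sz] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Clip a ray p(t) = o + t*d against the axis-aligned box [lo, hi]^3.
// Returns false when the ray misses the box.
static inline bool clip_ray(const double o[3], const double d[3],
                            const double lo[3], const double hi[3],
                            double& t0, double& t1) {
  t0 = -1e30; t1 = 1e30;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (o[a] < lo[a] || o[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - o[a]) / d[a];
      double tb = (hi[a] - o[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  return t1 > t0;
}

// Parallel-beam forward projection.
// vol: volume array dim (nx, ny, nz); voxel: voxel edge length (mm).
// uvec, vvec, dvec: 3 x n_angles matrices of detector basis / beam direction
// unit vectors in the object frame (object fixed, directions rotate).
// Detector has nrow x ncol pixels of pitch du (mm, object scale), centred on
// the rotation centre, which coincides with the volume centre.
// step: integration step as a fraction of the voxel size.
// Returns array (nrow, ncol, n_angles) of line integrals (dimensionless).
// [[Rcpp::export]]
NumericVector forward_project_cpp(NumericVector vol, IntegerVector dim3,
                                  double voxel,
                                  NumericMatrix uvec, NumericMatrix vvec,
                                  NumericMatrix dvec,
                                  int nrow, int ncol, double du, double step) {
  int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  int na = uvec.ncol();
  const double* v = REAL(vol);
  NumericVector out((R_xlen_t)nrow * ncol * na);
  double* o = REAL(out);
  // volume centre in fractional voxel coordinates
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double lo[3] = {-0.5, -0.5, -0.5};
  double hi[3] = {nx - 0.5, ny - 0.5, nz - 0.5};
  double h = step * voxel;          // step length in mm
  double hv = h / voxel;            // step length in voxels
  double u0 = -(ncol - 1) / 2.0 * du;
  double v0 = -(nrow - 1) / 2.0 * du;
  for (int a = 0; a < na; ++a) {
    double ux = uvec(0, a), uy = uvec(1, a), uz = uvec(2, a);
    double vx = vvec(0, a), vy = vvec(1, a), vz = vvec(2, a);
    double dx = dvec(0, a), dy = dvec(1, a), dz = dvec(2, a);
    double d[3] = {dx, dy, dz};
    double* frame = o + (R_xlen_t)a * nrow * ncol;
    for (int c = 0; c < ncol; ++c) {
      double uu = u0 + c * du;
      for (int r = 0; r < nrow; ++r) {
        double vv = v0 + r * du;
        // ray origin in voxel coordinates relative to grid
        double orr[3] = {cx + (uu * ux + vv * vx) / voxel,
                         cy + (uu * uy + vv * vy) / voxel,
                         cz + (uu * uz + vv * vz) / voxel};
        double t0, t1;
        if (!clip_ray(orr, d, lo, hi, t0, t1)) continue;
        int nstep = (int)std::ceil((t1 - t0) / hv);
        if (nstep < 1) nstep = 1;
        double hh = (t1 - t0) / nstep;      // voxel units
        double acc = 0.0;
        double t = t0 + 0.5 * hh;
        for (int s = 0; s < nstep; ++s, t += hh) {
          acc += trilinear(v, nx, ny, nz,
                           orr[0] + t * dx, orr[1] + t * dy, orr[2] + t * dz);
        }
        frame[c * nrow + r] = acc * hh * voxel;  // integral in mm * mu
      }
    }
  }
  return out;
}

// Voxel-driven backprojection of filtered frames.
// frames: (nrow, ncol, n_angles); geometry vectors as in forward_project_cpp.
// Output grid: dim (nx, ny, nz), voxel edge vox (mm), centred on the rotation
// centre. Each voxel accumulates the bilinear sample of every frame at its
// parallel projection (u, v) = (r.u(phi), r.v(phi)); caller applies the
// pi / n_angles FBP weight.
// [[Rcpp::export]]
NumericVector backproject_cpp(NumericVector frames, IntegerVector fdim,
                              NumericMatrix uvec, NumericMatrix vvec,
                              double du_col, double du_row,
                              IntegerVector dim3, double vox) {
  int nrow = fdim[0], ncol = fdim[1], na = fdim[2];
  int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  const double* f = REAL(frames);
  NumericVector out((R_xlen_t)nx * ny * nz);
  double* o = REAL(out);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double u0 = -(ncol - 1) / 2.0 * du_col;
  double v0 = -(nrow - 1) / 2.0 * du_row;
  for (int a = 0; a < na; ++a) {
    double ux = uvec(0, a), uy = uvec(1, a), uz = uvec(2, a);
    double vx = vvec(0, a), vy = vvec(1, a), vz = vvec(2, a);
    const double* frame = f + (R_xlen_t)a * nrow * ncol;
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      double pz = (k - cz) * vox;
      for (int j = 0; j < ny; ++j) {
        double py = (j - cy) * vox;
        for (int i = 0; i < nx; ++i, ++idx) {
          double px = (i - cx) * vox;
          double uu = px * ux + py * uy + pz * uz;
          double vv = px * vx + py * vy + pz * vz;
          double c = (uu - u0) / du_col;   // fractional column
          double r = (vv - v0) / du_row;   // fractional row
          if (c < 0 || r < 0 || c > ncol - 1 || r > nrow - 1) continue;
          int c0 = (int)std::floor(c); if (c0 > ncol - 2) c0 = ncol - 2;
          int r0 = (int)std::floor(r); if (r0 > nrow - 2) r0 = nrow - 2;
          double fc = c - c0, fr = r - r0;
          const double* p = frame + (R_xlen_t)c0 * nrow + r0;
          double val = p[0] * (1 - fc) * (1 - fr) + p[nrow] * fc * (1 - fr) +
                       p[1] * (1 - fc) * fr + p[nrow + 1] * fc * fr;
          o[idx] += val;
        }
      }
    }
  }
  return out;
}

// Affine trilinear resampling: for each target voxel index q (0-based),
// source index p = A %*% q + b (both in fractional voxel units); values
// outside the source grid get `fill`. Returns list(data, n_outside).
// [[Rcpp::export]]
List resample_affine_cpp(NumericVector src, IntegerVector sdim,
                         IntegerVector tdim, NumericMatrix A,
                         NumericVector b, double fill) {
  int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  const double* v = REAL(src);
  NumericVector out((R_xlen_t)tx * ty * tz);
  double* o = REAL(out);
  long n_out = 0;
  R_xlen_t idx = 0;
  for (int k = 0; k < tz; ++k)
    for (int j = 0; j < ty; ++j)
      for (int i = 0; i < tx; ++i, ++idx) {
        double x = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double y = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double z = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        if (x < 0 || y < 0 || z < 0 ||
            x > sx - 1.0 || y > sy - 1.0 || z > sz - 1.0) {
          o[idx] = fill; ++n_out;
        } else {
          o[idx] = trilinear(v, sx, sy, sz, x, y, z);
        }
      }
  return List::create(_["data"] = out, _["n_outside"] = n_out);
}

// Binary median filter with a box kernel of odd per-axis edges `sizes`;
// replicate padding at the grid edges. Odd window cardinality makes the
// count > half rule the exact median.
// [[Rcpp::export]]
LogicalVector binary_median3d_cpp(LogicalVector mask, IntegerVector dim3,
                                  IntegerVector sizes) {
  int nx = dim3[0], ny = dim3[1], nz = dim3[2];
  int hx = sizes[0] / 2, hy = sizes[1] / 2, hz = sizes[2] / 2;
  const int* m = LOGICAL(mask);
  LogicalVector out((R_xlen_t)nx * ny * nz);
  int* o = LOGICAL(out);
  int half = (sizes[0] * sizes[1] * sizes[2]) / 2;  // majority: count > half
  R_xlen_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        int cnt = 0;
        for (int dk = -hz; dk <= hz; ++dk) {
          int kk = k + dk; if (kk < 0) kk = 0; if (kk >= nz) kk = nz - 1;
          for (int dj = -hy; dj <= hy; ++dj) {
            int jj = j + dj; if (jj < 0) jj = 0; if (jj >= ny) jj = ny - 1;
            for (int di = -hx; di <= hx; ++di) {
              int ii = i + di; if (ii < 0) ii = 0; if (ii >= nx) ii = nx - 1;
              cnt += m[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)];
            }
          }
        }
        o[idx] = cnt > half;
      }
  return out;
}
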