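#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Trilinear sample of a volume at continuous voxel coordinates (clamped).
static double trilin(const NumericVector& v, int nx, int ny, int nz,
                     double x, double y, double z) {
  if (x < 0) x = 0; if (x > nx - 1) x = nx - 1;
  if (y < 0) y = 0; if (y > ny - 1) y = ny - 1;
  if (z < 0) z = 0; if (z > nz - 1) z = nz - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = x0 < nx - 1 ? x0 + 1 : x0;
  int y1 = y0 < ny - 1 ? y0 + 1 : y0;
  int z1 = z0 < nz - 1 ? z0 + 1 : z0;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  auto at = [&](int i, int j, int k) {
    return v[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
  };
  double c00 = at(x0, y0, z0) * (1 - fx) + at(x1, y0, z0) * fx;
  double c10 = at(x0, y1, z0) * (1 - fx) + at(x1, y1, z0) * fx;
  double c01 = at(x0, y0, z1) * (1 - fx) + at(x1, y0, z1) * fx;
  double c11 = at(x0, y1, z1) * (1 - fx) + at(x1, y1, z1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Gradient-projection thickness: from each pial seed voxel, march along the
// interpolated gradient of the exterior distance field `D` (which increases
// away from the background) until entering white matter; returns the path
// length in mm plus a half-voxel pial-side correction.  NA where the march
// leaves the grid or stalls; `cap_mm` bounds runaway rays.
// [[Rcpp::export(name = ".ray_thickness")]]
NumericVector ray_thickness(NumericVector D, IntegerVector dim,
                            NumericVector spacing, IntegerVector seeds,
                            LogicalVector wm, double step_vox, double cap_mm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double smin = std::min(sx, std::min(sy, sz));
  const double step_mm = step_vox * smin;
  const int n_seeds = seeds.size();
  NumericVector out(n_seeds);

  for (int s = 0; s < n_seeds; ++s) {
    R_xlen_t li = seeds[s];  // 0-based linear index
    double x = (double)(li % nx);
    double y = (double)((li / nx) % ny);
    double z = (double)(li / ((R_xlen_t)nx * ny));
    double travelled = 0.0;
    double res = NA_REAL;
    const double h = 0.5;  // central-difference half-width (voxels)
    while (travelled < cap_mm) {
      // gradient of D in mm^-1 units
      double gx = (trilin(D, nx, ny, nz, x + h, y, z) -
                   trilin(D, nx, ny, nz, x - h, y, z)) / (2 * h * sx);
      double gy = (trilin(D, nx, ny, nz, x, y + h, z) -
                   trilin(D, nx, ny, nz, x, y - h, z)) / (2 * h * sy);
      double gz = (trilin(D, nx, ny, nz, x, y, z + h) -
                   trilin(D, nx, ny, nz, x, y, z - h)) / (2 * h * sz);
      double gn = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (gn < 1e-8) break;  // flat field: stalled ray
      // advance step_mm along the gradient, in voxel coordinates
      x += (gx / gn) * step_mm / sx;
      y += (gy / gn) * step_mm / sy;
      z += (gz / gn) * step_mm / sz;
      travelled += step_mm;
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
        break;
      int xi = (int)std::lround(x), yi = (int)std::lround(y),
          zi = (int)std::lround(z);
      if (wm[(R_xlen_t)xi + (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi)]) {
        res = travelled + 0.5 * smin;  // pial-side half-voxel correction
        break;
      }
    }
    if (ISNA(res) && travelled >= cap_mm) res = cap_mm;
    out[s] = res;
  }
  return out;
}
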