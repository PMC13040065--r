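#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared Euclidean distance transform (lower envelope of parabolas),
// with samples at physical positions i * w.  f holds squared distances on
// input; d receives the transformed values.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;  // an infinite parabola never joins the envelope
    double s = 0.0;
    while (k >= 0) {
      int p = v[k];
      // intersection of parabolas rooted at p and q (positions scaled by w);
      // an infinite parabola at p is dominated by q everywhere
      s = (f[p] == INF) ? -INF
          : ((f[q] + w * w * q * q) - (f[p] + w * w * p * p)) /
            (2.0 * w * w * (q - p));
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform.  `mask` is the foreground
// (distance is measured from each foreground voxel to the nearest background
// voxel); background voxels get 0.  Returns distances in the units of
// `spacing`.  If there is no background voxel every distance is +Inf.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d2(n);
  for (R_xlen_t i = 0; i < n; ++i) d2[i] = mask[i] ? INF : 0.0;

  // pass along x
  {
    std::vector<double> f(nx), g(nx);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        for (int x = 0; x < nx; ++x) f[x] = d2[base + x];
        dt1d(f, g, nx, spacing[0]);
        for (int x = 0; x < nx; ++x) d2[base + x] = g[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), g(ny);
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * ny * z;
        for (int y = 0; y < ny; ++y) f[y] = d2[base + (R_xlen_t)nx * y];
        dt1d(f, g, ny, spacing[1]);
        for (int y = 0; y < ny; ++y) d2[base + (R_xlen_t)nx * y] = g[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(nz), g(nz);
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = x + (R_xlen_t)nx * y;
        for (int z = 0; z < nz; ++z) f[z] = d2[base + stride * z];
        dt1d(f, g, nz, spacing[2]);
        for (int z = 0; z < nz; ++z) d2[base + stride * z] = g[z];
      }
  }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(d2[i]);
  out.attr("dim") = dim;
  return out;
}
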