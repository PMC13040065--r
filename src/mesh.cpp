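#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>

using namespace Rcpp;

// Separable Gaussian smoothing of a 3D volume; values outside the grid are
// treated as 0, so a mask padded by the caller stays closed at the border.
// [[Rcpp::export(name = ".smooth3d")]]
NumericVector smooth3d(NumericVector vol, IntegerVector dim, double sigma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (sigma <= 0) {
    NumericVector copy = clone(vol);
    copy.attr("dim") = dim;
    return copy;
  }
  const int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> kern(2 * rad + 1);
  double ks = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    kern[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    ks += kern[i + rad];
  }
  for (double& k : kern) k /= ks;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int len = dims[axis];
    const R_xlen_t st = strides[axis];
    for (R_xlen_t i = 0; i < n; ++i) {
      // coordinate along this axis
      int c;
      if (axis == 0) c = (int)(i % nx);
      else if (axis == 1) c = (int)((i / nx) % ny);
      else c = (int)(i / ((R_xlen_t)nx * ny));
      double acc = 0.0;
      for (int j = -rad; j <= rad; ++j) {
        int cc = c + j;
        if (cc < 0 || cc >= len) continue;  // zero outside
        acc += kern[j + rad] * a[i + (R_xlen_t)j * st];
      }
      b[i] = acc;
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Kuhn decomposition of the unit cube into 6 tetrahedra sharing the main
// diagonal (corner 0 to corner 6); compatible across neighbouring cubes.
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
static const int CORN[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

struct MeshAcc {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
};

// vertex on the lattice edge (ia, ib): linear voxel indices, interpolated at
// `level`; welded so shared edges reuse the same vertex.
static int edge_vert(MeshAcc& m, uint64_t ia, uint64_t ib,
                     double va, double vb,
                     double ax, double ay, double az,
                     double bx, double by, double bz, double level) {
  uint64_t key = ia < ib ? (ia << 27) | ib : (ib << 27) | ia;
  auto it = m.edge_vertex.find(key);
  if (it != m.edge_vertex.end()) return it->second;
  double denom = vb - va;
  double t = std::abs(denom) < 1e-12 ? 0.5 : (level - va) / denom;
  if (t < 0) t = 0; if (t > 1) t = 1;
  m.vx.push_back(ax + t * (bx - ax));
  m.vy.push_back(ay + t * (by - ay));
  m.vz.push_back(az + t * (bz - az));
  int id = (int)m.vx.size() - 1;
  m.edge_vertex[key] = id;
  return id;
}

// Marching tetrahedra over a scalar volume at `level`; vertices returned in
// physical mm (index * spacing).  Produces a closed, consistently welded
// triangle mesh for any field that is below `level` on the whole border.
// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, IntegerVector dim, double level,
                NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  if ((R_xlen_t)nx * ny * nz >= ((R_xlen_t)1 << 27))
    stop("volume too large for mesh extraction (edge keys need < 2^27 voxels)");
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  MeshAcc m;

  std::vector<uint64_t> lin(8);
  std::vector<double> val(8);

  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double mn = 1e300, mx = -1e300;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CORN[c][0], cy = y + CORN[c][1], cz = z + CORN[c][2];
          uint64_t li = (uint64_t)cx + (uint64_t)nx * (cy + (uint64_t)ny * cz);
          lin[c] = li;
          val[c] = vol[li];
          if (val[c] < mn) mn = val[c];
          if (val[c] > mx) mx = val[c];
        }
        if (mn >= level || mx < level) continue;
        for (int t = 0; t < 6; ++t) {
          int tv[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int ins[4], outs[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (val[tv[k]] >= level) ins[ni++] = tv[k];
            else outs[no++] = tv[k];
          }
          if (ni == 0 || ni == 4) continue;
          auto P = [&](int c, double* p) {
            p[0] = (x + CORN[c][0]) * sx;
            p[1] = (y + CORN[c][1]) * sy;
            p[2] = (z + CORN[c][2]) * sz;
          };
          auto EV = [&](int a, int b) {
            double pa[3], pb[3];
            P(a, pa); P(b, pb);
            return edge_vert(m, lin[a], lin[b], val[a], val[b],
                             pa[0], pa[1], pa[2], pb[0], pb[1], pb[2], level);
          };
          if (ni == 1) {
            int v0 = EV(ins[0], outs[0]), v1 = EV(ins[0], outs[1]),
                v2 = EV(ins[0], outs[2]);
            m.tri.push_back(v0); m.tri.push_back(v1); m.tri.push_back(v2);
          } else if (ni == 3) {
            int v0 = EV(ins[0], outs[0]), v1 = EV(ins[1], outs[0]),
                v2 = EV(ins[2], outs[0]);
            m.tri.push_back(v0); m.tri.push_back(v1); m.tri.push_back(v2);
          } else {  // ni == 2: quad split into two triangles
            int vac = EV(ins[0], outs[0]), vad = EV(ins[0], outs[1]);
            int vbc = EV(ins[1], outs[0]), vbd = EV(ins[1], outs[1]);
            m.tri.push_back(vac); m.tri.push_back(vad); m.tri.push_back(vbd);
            m.tri.push_back(vac); m.tri.push_back(vbd); m.tri.push_back(vbc);
          }
        }
      }

  const int nv = (int)m.vx.size();
  NumericMatrix verts(nv, 3);
  for (int i = 0; i < nv; ++i) {
    verts(i, 0) = m.vx[i];
    verts(i, 1) = m.vy[i];
    verts(i, 2) = m.vz[i];
  }
  const int nf = (int)m.tri.size() / 3;
  IntegerMatrix faces(nf, 3);
  for (int i = 0; i < nf; ++i) {
    faces(i, 0) = m.tri[3 * i] + 1;     // 1-based for R
    faces(i, 1) = m.tri[3 * i + 1] + 1;
    faces(i, 2) = m.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}
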