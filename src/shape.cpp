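// Mask-derived shape support: closed surface mesh of a binary mask via
// marching tetrahedra on the 0.5 iso-level of a lightly smoothed indicator
// field (3x3x3 box filter; suppresses the voxelization staircase that
// otherwise inflates surface area), plus maximum 3D / in-plane diameters
// over surface voxels.
#include <Rcpp.h>
using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 sub(const V3& a, const V3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline V3 cross(const V3& a, const V3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

// point where the segment a(va) -> b(vb) crosses the 0.5 level
static inline V3 lerp05(const V3& a, double va, const V3& b, double vb) {
  double t = (0.5 - va) / (vb - va);
  return {a.x + t * (b.x - a.x), a.y + t * (b.y - a.y), a.z + t * (b.z - a.z)};
}

// accumulate one triangle, orienting its normal away from the inside centroid
static void add_tri(V3 p0, V3 p1, V3 p2, const V3& inside,
                    double& area, double& vol6) {
  V3 n = cross(sub(p1, p0), sub(p2, p0));
  V3 c = {(p0.x + p1.x + p2.x) / 3 - inside.x,
          (p0.y + p1.y + p2.y) / 3 - inside.y,
          (p0.z + p1.z + p2.z) / 3 - inside.z};
  if (dot(n, c) < 0) { V3 t = p1; p1 = p2; p2 = t; n = cross(sub(p1, p0), sub(p2, p0)); }
  area += 0.5 * std::sqrt(dot(n, n));
  // signed volume of tetrahedron (origin, p0, p1, p2); outward normals sum
  // to the enclosed volume by the divergence theorem
  vol6 += dot(p0, cross(p1, p2));
}

static void do_tet(const V3 p[4], const double v[4], double& area, double& vol6) {
  int in[4], ni = 0;
  for (int k = 0; k < 4; ++k) { in[k] = v[k] > 0.5; ni += in[k]; }
  if (ni == 0 || ni == 4) return;
  int ii[4], oo[4], a = 0, b = 0;
  for (int k = 0; k < 4; ++k) { if (in[k]) ii[a++] = k; else oo[b++] = k; }
  if (ni == 1) {
    int c = ii[0];
    add_tri(lerp05(p[c], v[c], p[oo[0]], v[oo[0]]),
            lerp05(p[c], v[c], p[oo[1]], v[oo[1]]),
            lerp05(p[c], v[c], p[oo[2]], v[oo[2]]), p[c], area, vol6);
  } else if (ni == 3) {
    int c = oo[0];
    V3 q0 = lerp05(p[ii[0]], v[ii[0]], p[c], v[c]);
    V3 q1 = lerp05(p[ii[1]], v[ii[1]], p[c], v[c]);
    V3 q2 = lerp05(p[ii[2]], v[ii[2]], p[c], v[c]);
    V3 cin = {(p[ii[0]].x + p[ii[1]].x + p[ii[2]].x) / 3,
              (p[ii[0]].y + p[ii[1]].y + p[ii[2]].y) / 3,
              (p[ii[0]].z + p[ii[1]].z + p[ii[2]].z) / 3};
    add_tri(q0, q1, q2, cin, area, vol6);
  } else {  // 2 in, 2 out: quad ordered around the perimeter, split in two
    int A = ii[0], B = ii[1], C = oo[0], D = oo[1];
    V3 cin = {(p[A].x + p[B].x) / 2, (p[A].y + p[B].y) / 2, (p[A].z + p[B].z) / 2};
    V3 q0 = lerp05(p[A], v[A], p[C], v[C]);
    V3 q1 = lerp05(p[A], v[A], p[D], v[D]);
    V3 q2 = lerp05(p[B], v[B], p[D], v[D]);
    V3 q3 = lerp05(p[B], v[B], p[C], v[C]);
    add_tri(q0, q1, q2, cin, area, vol6);
    add_tri(q0, q2, q3, cin, area, vol6);
  }
}

// 6-tetrahedra decomposition of a cell around the main diagonal (0 -> 7),
// corners indexed by bits (x=1, y=2, z=4)
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
};

// field: smoothed indicator, zero-padded so the iso-surface is closed
// [[Rcpp::export]]
List cpp_surface_mesh(NumericVector field, IntegerVector dims,
                      NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  auto val = [&](int x, int y, int z) -> double {
    return field[x + (size_t)nx * (y + (size_t)ny * z)];
  };
  double area = 0.0, vol6 = 0.0;
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double v[8]; int nin = 0;
        for (int c = 0; c < 8; ++c) {
          v[c] = val(x + (c & 1), y + ((c >> 1) & 1), z + ((c >> 2) & 1));
          nin += v[c] > 0.5;
        }
        if (nin == 0 || nin == 8) continue;
        V3 pc[8];
        for (int c = 0; c < 8; ++c)
          pc[c] = {(x + (c & 1)) * sx, (y + ((c >> 1) & 1)) * sy,
                   (z + ((c >> 2) & 1)) * sz};
        for (int t = 0; t < 6; ++t) {
          V3 tp[4]; double tv[4];
          for (int k = 0; k < 4; ++k) { tp[k] = pc[TETS[t][k]]; tv[k] = v[TETS[t][k]]; }
          do_tet(tp, tv, area, vol6);
        }
      }
  return List::create(_["area"] = area, _["volume"] = std::fabs(vol6) / 6.0);
}

// separable 3-wide box filter with zero boundary
// [[Rcpp::export]]
NumericVector cpp_box_smooth(NumericVector values, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> a(values.begin(), values.end()), b(n);
  auto pass = [&](std::vector<double>& src, std::vector<double>& dst,
                  int stride, int len, int nline, const std::vector<size_t>& base) {
    for (int l = 0; l < nline; ++l) {
      size_t o = base[l];
      for (int i = 0; i < len; ++i) {
        double s = src[o + (size_t)i * stride];
        if (i > 0) s += src[o + (size_t)(i - 1) * stride];
        if (i < len - 1) s += src[o + (size_t)(i + 1) * stride];
        dst[o + (size_t)i * stride] = s / 3.0;
      }
    }
  };
  std::vector<size_t> base;
  base.reserve((size_t)ny * nz);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) base.push_back((size_t)nx * (y + (size_t)ny * z));
  pass(a, b, 1, nx, (int)base.size(), base);
  base.clear();
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) base.push_back(x + (size_t)nx * ny * z);
  pass(b, a, nx, ny, (int)base.size(), base);
  base.clear();
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) base.push_back(x + (size_t)nx * y);
  pass(a, b, nx * ny, nz, (int)base.size(), base);
  return NumericVector(b.begin(), b.end());
}

// max pairwise distances over surface-voxel coordinates (physical, mm):
// full 3D plus the three in-plane diameters (pairs sharing a slice index)
// [[Rcpp::export]]
NumericVector cpp_max_diameters(NumericMatrix xyz, IntegerMatrix ijk) {
  int n = xyz.nrow();
  double d3 = 0, dxy = 0, dxz = 0, dyz = 0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double dx = xyz(a, 0) - xyz(b, 0);
      double dy = xyz(a, 1) - xyz(b, 1);
      double dz = xyz(a, 2) - xyz(b, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > d3) d3 = d2;
      if (ijk(a, 2) == ijk(b, 2) && dx * dx + dy * dy > dxy) dxy = dx * dx + dy * dy;
      if (ijk(a, 1) == ijk(b, 1) && dx * dx + dz * dz > dxz) dxz = dx * dx + dz * dz;
      if (ijk(a, 0) == ijk(b, 0) && dy * dy + dz * dz > dyz) dyz = dy * dy + dz * dz;
    }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dxy),
                               std::sqrt(dxz), std::sqrt(dyz));
}
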