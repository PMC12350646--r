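#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Large finite stand-in for +Inf so the lower-envelope recursion in the
// distance transform never forms Inf - Inf.
static const double BIG = 1e20;

// ---------------------------------------------------------------------------
// Exact 1-D squared Euclidean distance transform (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher) with physical sample spacing s.
// f holds squared distances at positions i*s; d receives the transform.
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double s) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    for (;;) {
      double xv = v[k] * s;
      double inter = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (inter <= z[k]) {
        if (k == 0) {
          // the new parabola undercuts the envelope everywhere (the old
          // root sat at BIG): replace the root instead of leaving the
          // envelope (k must never go below 0)
          v[0] = q;
          z[1] = BIG;
          break;
        }
        --k;
      } else {
        ++k;
        v[k] = q;
        z[k] = inter;
        z[k + 1] = BIG;
        break;
      }
    }
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest voxel
// with vox == 1, honouring anisotropic spacing. All-zero input gives BIG.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector vox, IntegerVector dim,
                         NumericVector spacing) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = vox[i] == 1 ? 0.0 : BIG;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (stride 1)
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      R_xlen_t base = (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k);
      for (int i = 0; i < n1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, n1, spacing[0]);
      for (int i = 0; i < n1; ++i) out[base + i] = d[i];
    }
  // axis 2 (stride n1)
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * n2 * k;
      for (int j = 0; j < n2; ++j) f[j] = out[base + (R_xlen_t)n1 * j];
      dt1d(f, d, v, z, n2, spacing[1]);
      for (int j = 0; j < n2; ++j) out[base + (R_xlen_t)n1 * j] = d[j];
    }
  // axis 3 (stride n1*n2)
  R_xlen_t s3 = (R_xlen_t)n1 * n2;
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      R_xlen_t base = i + (R_xlen_t)n1 * j;
      for (int k = 0; k < n3; ++k) f[k] = out[base + s3 * k];
      dt1d(f, d, v, z, n3, spacing[2]);
      for (int k = 0; k < n3; ++k) out[base + s3 * k] = d[k];
    }
  return out;
}

// Background voxels (vox == 0) 6-connected to the array border: returns 1
// there, 0 elsewhere. Used for cancellous-fill (internal cavities are the
// background voxels NOT reached).
// [[Rcpp::export]]
IntegerVector cpp_border_background(IntegerVector vox, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  IntegerVector reach(n);
  std::vector<int64_t> stack;
  stack.reserve(1 << 16);

  auto idx = [&](int i, int j, int k) {
    return (int64_t)i + (int64_t)n1 * (j + (int64_t)n2 * k);
  };
  auto push = [&](int i, int j, int k) {
    int64_t id = idx(i, j, k);
    if (vox[id] == 0 && reach[id] == 0) { reach[id] = 1; stack.push_back(id); }
  };
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      push(0, j, k);
      push(n1 - 1, j, k);
    }
  for (int k = 0; k < n3; ++k)
    for (int i = 0; i < n1; ++i) {
      push(i, 0, k);
      push(i, n2 - 1, k);
    }
  for (int j = 0; j < n2; ++j)
    for (int i = 0; i < n1; ++i) {
      push(i, j, 0);
      push(i, j, n3 - 1);
    }
  while (!stack.empty()) {
    int64_t id = stack.back();
    stack.pop_back();
    int i = (int)(id % n1);
    int64_t r = id / n1;
    int j = (int)(r % n2);
    int k = (int)(r / n2);
    if (i > 0) push(i - 1, j, k);
    if (i < n1 - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < n2 - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < n3 - 1) push(i, j, k + 1);
  }
  return reach;
}

// Shared geometry helper: for output voxel (i,j,k) of the reference lattice
// the continuous source index is cb + i*c1 + j*c2 + k*c3. The caller passes
// the INVERSE spatial map (source_world = Rinv * ref_world + tinv); this
// routine folds lattice geometry on both sides into the affine coefficients.
struct IndexMap {
  double cb[3], c1[3], c2[3], c3[3];
};

static IndexMap make_index_map(NumericVector sspacing, NumericVector sorigin,
                               NumericVector saxes, NumericVector rspacing,
                               NumericVector rorigin, NumericVector raxes,
                               NumericVector Rinv, NumericVector tinv) {
  // world position of ref voxel: x = ro + RA * (i*rs1, j*rs2, k*rs3)
  // source world: y = Rinv x + tinv
  // source index: c = SA^T (y - so) / ss   (SA orthonormal columns)
  IndexMap m;
  double b[3], e1[3], e2[3], e3[3];
  for (int a = 0; a < 3; ++a) {
    b[a] = tinv[a];
    for (int c = 0; c < 3; ++c) b[a] += Rinv[a + 3 * c] * rorigin[c];
    e1[a] = 0.0; e2[a] = 0.0; e3[a] = 0.0;
    for (int c = 0; c < 3; ++c) {
      e1[a] += Rinv[a + 3 * c] * raxes[c + 0] * rspacing[0];
      e2[a] += Rinv[a + 3 * c] * raxes[c + 3] * rspacing[1];
      e3[a] += Rinv[a + 3 * c] * raxes[c + 6] * rspacing[2];
    }
  }
  for (int a = 0; a < 3; ++a) {
    double cb = 0.0, c1 = 0.0, c2 = 0.0, c3 = 0.0;
    for (int c = 0; c < 3; ++c) {
      double col = saxes[c + 3 * a];  // SA^T row a = column a of saxes
      cb += col * (b[c] - sorigin[c]);
      c1 += col * e1[c];
      c2 += col * e2[c];
      c3 += col * e3[c];
    }
    m.cb[a] = cb / sspacing[a];
    m.c1[a] = c1 / sspacing[a];
    m.c2[a] = c2 / sspacing[a];
    m.c3[a] = c3 / sspacing[a];
  }
  return m;
}

// Nearest-neighbour resampling of a binary (or label) volume onto a
// reference lattice through an inverse rigid/reflective map.
// [[Rcpp::export]]
IntegerVector cpp_resample_nn(IntegerVector vox, IntegerVector sdim,
                              NumericVector sspacing, NumericVector sorigin,
                              NumericVector saxes, IntegerVector rdim,
                              NumericVector rspacing, NumericVector rorigin,
                              NumericVector raxes, NumericVector Rinv,
                              NumericVector tinv) {
  IndexMap m = make_index_map(sspacing, sorigin, saxes, rspacing, rorigin,
                              raxes, Rinv, tinv);
  int n1 = rdim[0], n2 = rdim[1], n3 = rdim[2];
  int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  IntegerVector out((R_xlen_t)n1 * n2 * n3);
  R_xlen_t p = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double cx = m.cb[0] + j * m.c2[0] + k * m.c3[0];
      double cy = m.cb[1] + j * m.c2[1] + k * m.c3[1];
      double cz = m.cb[2] + j * m.c2[2] + k * m.c3[2];
      for (int i = 0; i < n1; ++i, ++p) {
        long ii = std::lround(cx + i * m.c1[0]);
        long jj = std::lround(cy + i * m.c1[1]);
        long kk = std::lround(cz + i * m.c1[2]);
        if (ii >= 0 && ii < s1 && jj >= 0 && jj < s2 && kk >= 0 && kk < s3)
          out[p] = vox[ii + (R_xlen_t)s1 * (jj + (R_xlen_t)s2 * kk)];
      }
    }
  return out;
}

static inline double trilinear(const double* vals, int s1, int s2, int s3,
                               double x, double y, double z, double fill) {
  if (x < -0.5 || y < -0.5 || z < -0.5 || x > s1 - 0.5 || y > s2 - 0.5 ||
      z > s3 - 0.5)
    return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk) {
    int kk = k0 + dk;
    if (kk < 0 || kk >= s3) { if ((dk ? fz : 1 - fz) != 0 && fill != 0) acc += fill * (dk ? fz : 1 - fz); continue; }
    double wz = dk ? fz : 1 - fz;
    if (wz == 0) continue;
    for (int dj = 0; dj < 2; ++dj) {
      int jj = j0 + dj;
      double wy = dj ? fy : 1 - fy;
      if (wy == 0) continue;
      if (jj < 0 || jj >= s2) { acc += fill * wz * wy; continue; }
      for (int di = 0; di < 2; ++di) {
        int ii = i0 + di;
        double wx = di ? fx : 1 - fx;
        if (wx == 0) continue;
        double v = (ii < 0 || ii >= s1)
                       ? fill
                       : vals[ii + (R_xlen_t)s1 * (jj + (R_xlen_t)s2 * kk)];
        acc += v * wz * wy * wx;
      }
    }
  }
  return acc;
}

// Trilinear resampling of a grey volume onto a reference lattice.
// [[Rcpp::export]]
NumericVector cpp_resample_lin(NumericVector vals, IntegerVector sdim,
                               NumericVector sspacing, NumericVector sorigin,
                               NumericVector saxes, IntegerVector rdim,
                               NumericVector rspacing, NumericVector rorigin,
                               NumericVector raxes, NumericVector Rinv,
                               NumericVector tinv, double fill) {
  IndexMap m = make_index_map(sspacing, sorigin, saxes, rspacing, rorigin,
                              raxes, Rinv, tinv);
  int n1 = rdim[0], n2 = rdim[1], n3 = rdim[2];
  int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  const double* vp = REAL(vals);
  R_xlen_t p = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      double cx = m.cb[0] + j * m.c2[0] + k * m.c3[0];
      double cy = m.cb[1] + j * m.c2[1] + k * m.c3[1];
      double cz = m.cb[2] + j * m.c2[2] + k * m.c3[2];
      for (int i = 0; i < n1; ++i, ++p)
        out[p] = trilinear(vp, s1, s2, s3, cx + i * m.c1[0], cy + i * m.c1[1],
                           cz + i * m.c1[2], fill);
    }
  return out;
}

// Registration objective kernel: weighted sum over fixed-model sample
// points (columns of pts, world mm; weights = fixed foreground fraction)
// of the trilinearly interpolated moving model after applying the
// candidate map (passed as its inverse).
// [[Rcpp::export]]
double cpp_overlap_mass(NumericVector mvals, IntegerVector sdim,
                        NumericVector sspacing, NumericVector sorigin,
                        NumericVector saxes, NumericMatrix pts,
                        NumericVector wts, NumericVector Rinv,
                        NumericVector tinv) {
  int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  const double* vp = REAL(mvals);
  // fold source geometry: c = SA^T (y - so)/ss with y = Rinv p + tinv
  double A[9], b[3];
  for (int a = 0; a < 3; ++a) {
    double bb = 0.0;
    for (int c = 0; c < 3; ++c) bb += saxes[c + 3 * a] * (tinv[c] - sorigin[c]);
    b[a] = bb / sspacing[a];
    for (int c = 0; c < 3; ++c) {
      double acc = 0.0;
      for (int q = 0; q < 3; ++q) acc += saxes[q + 3 * a] * Rinv[q + 3 * c];
      A[a + 3 * c] = acc / sspacing[a];
    }
  }
  double total = 0.0;
  int n = pts.ncol();
  const double* P = REAL(pts);
  for (int t = 0; t < n; ++t) {
    double px = P[3 * t], py = P[3 * t + 1], pz = P[3 * t + 2];
    double x = A[0] * px + A[3] * py + A[6] * pz + b[0];
    double y = A[1] * px + A[4] * py + A[7] * pz + b[1];
    double z = A[2] * px + A[5] * py + A[8] * pz + b[2];
    total += wts[t] * trilinear(vp, s1, s2, s3, x, y, z, 0.0);
  }
  return total;
}

// One 7-point (self + 6 neighbours, equal weights) smoothing pass.
// Removes the voxel-scale roughness of rasterized masks so that the
// interpolated registration objective has no lattice-phase bias.
// [[Rcpp::export]]
NumericVector cpp_smooth7(NumericVector vals, IntegerVector dim) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  const double w = 1.0 / 7.0;
  R_xlen_t p = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++p) {
        double s = vals[p];
        s += (i > 0) ? vals[p - 1] : vals[p];
        s += (i < n1 - 1) ? vals[p + 1] : vals[p];
        s += (j > 0) ? vals[p - n1] : vals[p];
        s += (j < n2 - 1) ? vals[p + n1] : vals[p];
        s += (k > 0) ? vals[p - (R_xlen_t)n1 * n2] : vals[p];
        s += (k < n3 - 1) ? vals[p + (R_xlen_t)n1 * n2] : vals[p];
        out[p] = s * w;
      }
  return out;
}

// Non-overlapping block means (box-filter pyramid level) of a 3-D volume;
// trailing partial blocks are dropped.
// [[Rcpp::export]]
NumericVector cpp_block_mean(IntegerVector vox, IntegerVector dim, int f) {
  int n1 = dim[0] / f, n2 = dim[1] / f, n3 = dim[2] / f;
  int d1 = dim[0], d2 = dim[1];
  NumericVector out((R_xlen_t)n1 * n2 * n3);
  double inv = 1.0 / (f * f * f);
  R_xlen_t p = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i, ++p) {
        long s = 0;
        for (int kk = k * f; kk < (k + 1) * f; ++kk)
          for (int jj = j * f; jj < (j + 1) * f; ++jj) {
            R_xlen_t base = (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk) + i * f;
            for (int ii = 0; ii < f; ++ii) s += vox[base + ii];
          }
        out[p] = s * inv;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Phantom membership rasterizer: evaluates the analytic anatomy (arch,
// cleft wedge, graft wedge, tooth spheres, soft-tissue cylinder) at the
// mapped anatomical coordinates y = R x + t of every voxel centre and
// returns a bit mask per voxel: 1 bone, 2 cleft, 4 graft, 8 teeth, 16 head.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_phantom_shapes(IntegerVector dim, NumericVector spacing,
                                 NumericVector origin, NumericVector map_r,
                                 NumericVector map_t, double cy, double r_in,
                                 double r_out, double span_half,
                                 double z_half, double phic, double halfang,
                                 double r_floor, double g_halfang,
                                 double g_rlo, double g_rhi, bool has_cleft,
                                 bool has_graft, NumericMatrix teeth,
                                 double tooth_r, double head_r,
                                 double head_z) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  IntegerVector out((R_xlen_t)n1 * n2 * n3);
  int nt = teeth.ncol();
  double tr2 = tooth_r * tooth_r;
  R_xlen_t p = 0;
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j) {
      // world x = origin + (i*s1, j*s2, k*s3) on an axis-aligned lattice
      double bx = origin[0], by = origin[1] + j * spacing[1],
             bz = origin[2] + k * spacing[2];
      // anatomical coords y = R * world + t, incremental in i
      double ax = map_r[0] * bx + map_r[3] * by + map_r[6] * bz + map_t[0];
      double ay = map_r[1] * bx + map_r[4] * by + map_r[7] * bz + map_t[1];
      double az = map_r[2] * bx + map_r[5] * by + map_r[8] * bz + map_t[2];
      double dx_ = map_r[0] * spacing[0], dy_ = map_r[1] * spacing[0],
             dz_ = map_r[2] * spacing[0];
      for (int i = 0; i < n1; ++i, ++p, ax += dx_, ay += dy_, az += dz_) {
        double dy = ay - cy;
        double r2 = ax * ax + dy * dy;
        int code = 0;
        double absz = std::fabs(az);
        if (r2 <= head_r * head_r && absz <= head_z) code |= 16;
        bool in_z = absz <= z_half;
        double r_max = std::max(r_out, g_rhi);
        if (in_z && r2 >= std::min(r_in, g_rlo) * std::min(r_in, g_rlo) &&
            r2 <= r_max * r_max) {
          double r = std::sqrt(r2);
          double phi = std::atan2(ax, -dy);
          bool arch = r >= r_in && r <= r_out && std::fabs(phi) <= span_half;
          bool cleft = has_cleft && std::fabs(phi - phic) <= halfang &&
                       r >= r_floor && r <= r_out;
          if (arch && !cleft) code |= 1;
          if (arch && cleft) code |= 2;
          if (has_graft && std::fabs(phi - phic) <= g_halfang &&
              r >= g_rlo && r <= g_rhi)
            code |= 4;
        }
        for (int t = 0; t < nt; ++t) {
          double ddx = ax - teeth(0, t), ddy = ay - teeth(1, t),
                 ddz = az - teeth(2, t);
          if (ddx * ddx + ddy * ddy + ddz * ddz <= tr2) {
            code |= 8;
            break;
          }
        }
        out[p] = code;
      }
    }
  return out;
}

// ---------------------------------------------------------------------------
// Iso-surface (0.5 level) of a binary volume by marching tetrahedra on the
// Kuhn 6-tetrahedra cube decomposition, which tiles space consistently so
// the resulting surface is watertight. The volume is implicitly zero-padded
// so surfaces are closed at the array border. Returns an (3*ntri) x 3 matrix
// of world-coordinate vertices, one triangle per 3 consecutive rows,
// wound so normals point outward (from 1-voxels to 0-voxels).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_march_tets(IntegerVector vox, IntegerVector dim,
                             NumericVector spacing, NumericVector origin,
                             NumericVector axes) {
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  auto val = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= n1 || j >= n2 || k >= n3) return 0;
    return vox[i + (R_xlen_t)n1 * (j + (R_xlen_t)n2 * k)];
  };
  // cube corner offsets
  static const int co[8][3] = {{0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
                               {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}};
  static const int tets[6][4] = {{0, 1, 2, 6}, {0, 2, 3, 6}, {0, 3, 7, 6},
                                 {0, 7, 4, 6}, {0, 4, 5, 6}, {0, 5, 1, 6}};
  std::vector<double> tri;  // flat x,y,z per vertex (index space)
  tri.reserve(1 << 16);

  double P[4][3];  // tet corner positions (index space)
  int tv[4];
  auto emit = [&](const double* a, const double* b2, const double* c,
                  const double* in_c, const double* out_c) {
    // wind so normal points from inside centroid toward outside centroid
    double u[3], v[3], nrm[3], d[3];
    for (int q = 0; q < 3; ++q) {
      u[q] = b2[q] - a[q];
      v[q] = c[q] - a[q];
      d[q] = out_c[q] - in_c[q];
    }
    nrm[0] = u[1] * v[2] - u[2] * v[1];
    nrm[1] = u[2] * v[0] - u[0] * v[2];
    nrm[2] = u[0] * v[1] - u[1] * v[0];
    double dp = nrm[0] * d[0] + nrm[1] * d[1] + nrm[2] * d[2];
    if (dp >= 0) {
      for (int q = 0; q < 3; ++q) tri.push_back(a[q]);
      for (int q = 0; q < 3; ++q) tri.push_back(b2[q]);
      for (int q = 0; q < 3; ++q) tri.push_back(c[q]);
    } else {
      for (int q = 0; q < 3; ++q) tri.push_back(a[q]);
      for (int q = 0; q < 3; ++q) tri.push_back(c[q]);
      for (int q = 0; q < 3; ++q) tri.push_back(b2[q]);
    }
  };

  for (int k = -1; k < n3; ++k)
    for (int j = -1; j < n2; ++j)
      for (int i = -1; i < n1; ++i) {
        int cv[8];
        int any = 0, all = 1;
        for (int c = 0; c < 8; ++c) {
          cv[c] = val(i + co[c][0], j + co[c][1], k + co[c][2]);
          any |= cv[c];
          all &= cv[c];
        }
        if (!any || all) continue;
        for (int t = 0; t < 6; ++t) {
          int nin = 0;
          for (int c = 0; c < 4; ++c) {
            int corner = tets[t][c];
            tv[c] = cv[corner];
            P[c][0] = i + co[corner][0];
            P[c][1] = j + co[corner][1];
            P[c][2] = k + co[corner][2];
            nin += tv[c];
          }
          if (nin == 0 || nin == 4) continue;
          double inc[3] = {0, 0, 0}, outc[3] = {0, 0, 0};
          for (int c = 0; c < 4; ++c)
            for (int q = 0; q < 3; ++q)
              (tv[c] ? inc : outc)[q] += P[c][q];
          int nout = 4 - nin;
          for (int q = 0; q < 3; ++q) {
            inc[q] /= nin;
            outc[q] /= nout;
          }
          auto mid = [&](int a, int b2, double* m) {
            for (int q = 0; q < 3; ++q) m[q] = 0.5 * (P[a][q] + P[b2][q]);
          };
          if (nin == 1 || nin == 3) {
            int lone = -1;
            int want = (nin == 1) ? 1 : 0;
            for (int c = 0; c < 4; ++c)
              if (tv[c] == want) lone = c;
            double m0[3], m1[3], m2[3];
            int others[3], oi = 0;
            for (int c = 0; c < 4; ++c)
              if (c != lone) others[oi++] = c;
            mid(lone, others[0], m0);
            mid(lone, others[1], m1);
            mid(lone, others[2], m2);
            emit(m0, m1, m2, inc, outc);
          } else {  // 2 in, 2 out -> quad
            int ins[2], outs[2], ii2 = 0, oo = 0;
            for (int c = 0; c < 4; ++c)
              (tv[c] ? ins[ii2++] : outs[oo++]) = c;
            double q0[3], q1[3], q2[3], q3[3];
            mid(ins[0], outs[0], q0);
            mid(ins[0], outs[1], q1);
            mid(ins[1], outs[1], q2);
            mid(ins[1], outs[0], q3);
            emit(q0, q1, q2, inc, outc);
            emit(q0, q2, q3, inc, outc);
          }
        }
      }

  R_xlen_t nv = tri.size() / 3;
  NumericMatrix out(nv, 3);
  for (R_xlen_t r = 0; r < nv; ++r) {
    double xi = tri[3 * r], yj = tri[3 * r + 1], zk = tri[3 * r + 2];
    double lx = xi * spacing[0], ly = yj * spacing[1], lz = zk * spacing[2];
    for (int a = 0; a < 3; ++a)
      out(r, a) =
          origin[a] + axes[a + 0] * lx + axes[a + 3] * ly + axes[a + 6] * lz;
  }
  return out;
}
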