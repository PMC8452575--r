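#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel indexing follows R column-major order: i = x + nx*(y + ny*z).

static inline int wrap_index(int i, int n, int boundary) {
  // boundary: 0 = reflect (edge repeated, scipy-style), 1 = periodic
  if (boundary == 1) {
    i %= n;
    if (i < 0) i += n;
    return i;
  }
  // reflect: ... d c b a | a b c d | d c b a ...
  if (n == 1) return 0;
  int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : (period - 1 - i);
}

// Separable correlation along one axis (0-based), kernel centred at len/2.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector arr, IntegerVector dim,
                            NumericVector kernel, int axis, int boundary) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nk = kernel.size(), c = nk / 2;
  int n_axis = dim[axis];
  NumericVector out(arr.size());
  std::vector<double> line(n_axis), res(n_axis);
  int stride = (axis == 0) ? 1 : (axis == 1 ? nx : nx * ny);
  int n1 = (axis == 0) ? ny : nx;
  int n2 = (axis == 2) ? ny : nz;
  int s1 = (axis == 0) ? nx : 1;
  int s2 = (axis == 2) ? nx : nx * ny;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      int base = a * s1 + b * s2;
      for (int t = 0; t < n_axis; ++t) line[t] = arr[base + t * stride];
      for (int t = 0; t < n_axis; ++t) {
        double acc = 0.0;
        for (int k = 0; k < nk; ++k)
          acc += kernel[k] * line[wrap_index(t + k - c, n_axis, boundary)];
        res[t] = acc;
      }
      for (int t = 0; t < n_axis; ++t) out[base + t * stride] = res[t];
    }
  }
  return out;
}

// Trilinear resampling onto a voxel-centre-aligned grid. ratio[a] is
// target_spacing / input_spacing along axis a; input coordinate of output
// voxel j is u = (j + 0.5) * ratio - 0.5, clamped to the input grid.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector arr, IntegerVector dim,
                                     NumericVector ratio, IntegerVector outdim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((double)ox * oy * oz);
  std::vector<int> ix0(ox), iy0(oy), iz0(oz);
  std::vector<double> fx(ox), fy(oy), fz(oz);
  for (int j = 0; j < ox; ++j) {
    double u = (j + 0.5) * ratio[0] - 0.5;
    u = std::min(std::max(u, 0.0), (double)(nx - 1));
    ix0[j] = std::min((int)std::floor(u), nx - 2 >= 0 ? nx - 2 : 0);
    if (nx == 1) ix0[j] = 0;
    fx[j] = u - ix0[j];
  }
  for (int j = 0; j < oy; ++j) {
    double u = (j + 0.5) * ratio[1] - 0.5;
    u = std::min(std::max(u, 0.0), (double)(ny - 1));
    iy0[j] = std::min((int)std::floor(u), ny - 2 >= 0 ? ny - 2 : 0);
    if (ny == 1) iy0[j] = 0;
    fy[j] = u - iy0[j];
  }
  for (int j = 0; j < oz; ++j) {
    double u = (j + 0.5) * ratio[2] - 0.5;
    u = std::min(std::max(u, 0.0), (double)(nz - 1));
    iz0[j] = std::min((int)std::floor(u), nz - 2 >= 0 ? nz - 2 : 0);
    if (nz == 1) iz0[j] = 0;
    fz[j] = u - iz0[j];
  }
  for (int z = 0; z < oz; ++z) {
    int z0 = iz0[z], z1 = (nz > 1) ? z0 + 1 : z0;
    double wz = fz[z];
    for (int y = 0; y < oy; ++y) {
      int y0 = iy0[y], y1 = (ny > 1) ? y0 + 1 : y0;
      double wy = fy[y];
      for (int x = 0; x < ox; ++x) {
        int x0 = ix0[x], x1 = (nx > 1) ? x0 + 1 : x0;
        double wx = fx[x];
        double c00 = arr[x0 + nx * (y0 + ny * z0)] * (1 - wx) + arr[x1 + nx * (y0 + ny * z0)] * wx;
        double c10 = arr[x0 + nx * (y1 + ny * z0)] * (1 - wx) + arr[x1 + nx * (y1 + ny * z0)] * wx;
        double c01 = arr[x0 + nx * (y0 + ny * z1)] * (1 - wx) + arr[x1 + nx * (y0 + ny * z1)] * wx;
        double c11 = arr[x0 + nx * (y1 + ny * z1)] * (1 - wx) + arr[x1 + nx * (y1 + ny * z1)] * wx;
        double c0 = c00 * (1 - wy) + c10 * wy;
        double c1 = c01 * (1 - wy) + c11 * wy;
        out[x + ox * (y + (double)oy * z)] = c0 * (1 - wz) + c1 * wz;
      }
    }
  }
  return out;
}

static const int OFFS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Grey-level co-occurrence: counts per direction (symmetric), normalised per
// direction, then averaged over directions that contain at least one pair.
// levels: 0 outside ROI, 1..ng inside.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix avg(ng, ng);
  std::vector<double> cnt((size_t)ng * ng);
  int nvalid = 0;
  for (int d = 0; d < 13; ++d) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    double tot = 0.0;
    int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[x + nx * (y + ny * z)];
          if (li == 0) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          int lj = levels[x2 + nx * (y2 + ny * z2)];
          if (lj == 0) continue;
          cnt[(li - 1) + (size_t)ng * (lj - 1)] += 1.0;
          cnt[(lj - 1) + (size_t)ng * (li - 1)] += 1.0;
          tot += 2.0;
        }
    if (tot > 0) {
      ++nvalid;
      for (int j = 0; j < ng; ++j)
        for (int i = 0; i < ng; ++i)
          avg(i, j) += cnt[i + (size_t)ng * j] / tot;
    }
  }
  if (nvalid > 0)
    for (int j = 0; j < ng; ++j)
      for (int i = 0; i < ng; ++i) avg(i, j) /= nvalid;
  return avg;
}

// Run-length matrices, one ng x maxrun matrix per direction.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxrun = std::max(nx, std::max(ny, nz));
  List out(13);
  for (int d = 0; d < 13; ++d) {
    NumericMatrix m(ng, maxrun);
    int dx = OFFS[d][0], dy = OFFS[d][1], dz = OFFS[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int li = levels[x + nx * (y + ny * z)];
          if (li == 0) continue;
          // run start: predecessor along -d is absent or different level
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < nx && yp >= 0 && yp < ny && zp >= 0 && zp < nz &&
              levels[xp + nx * (yp + ny * zp)] == li)
            continue;
          int len = 1;
          int xc = x + dx, yc = y + dy, zc = z + dz;
          while (xc >= 0 && xc < nx && yc >= 0 && yc < ny && zc >= 0 && zc < nz &&
                 levels[xc + nx * (yc + ny * zc)] == li) {
            ++len; xc += dx; yc += dy; zc += dz;
          }
          m(li - 1, len - 1) += 1.0;
        }
    out[d] = m;
  }
  return out;
}

// Size-zone decomposition: 26-connected components of constant level.
// Returns a two-column matrix (level, zone size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm_zones(IntegerVector levels, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int i = 0; i < n; ++i) {
    if (levels[i] == 0 || seen[i]) continue;
    int lev = levels[i], size = 0;
    stack.clear(); stack.push_back(i); seen[i] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back(); ++size;
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int j = x2 + nx * (y2 + ny * z2);
            if (!seen[j] && levels[j] == lev) { seen[j] = 1; stack.push_back(j); }
          }
    }
    zl.push_back(lev); zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) { out(k, 0) = zl[k]; out(k, 1) = zs[k]; }
  return out;
}

// Neighbourhood grey-tone difference: per level, occupancy n_i and summed
// absolute difference s_i from the mean of the in-ROI 26-neighbourhood.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector levels, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2); // columns: n_i, s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int li = levels[x + nx * (y + ny * z)];
        if (li == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int lj = levels[x2 + nx * (y2 + ny * z2)];
              if (lj > 0) { sum += lj; ++cnt; }
            }
        out(li - 1, 0) += 1.0;
        if (cnt > 0) out(li - 1, 1) += std::fabs(li - sum / cnt);
      }
  return out;
}

static inline double tet_vol(const double a[3], const double b[3],
                             const double c[3], const double d[3]) {
  double u[3] = {a[0] - d[0], a[1] - d[1], a[2] - d[2]};
  double v[3] = {b[0] - d[0], b[1] - d[1], b[2] - d[2]};
  double w[3] = {c[0] - d[0], c[1] - d[1], c[2] - d[2]};
  double det = u[0] * (v[1] * w[2] - v[2] * w[1])
             - u[1] * (v[0] * w[2] - v[2] * w[0])
             + u[2] * (v[0] * w[1] - v[1] * w[0]);
  return std::fabs(det) / 6.0;
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double cx = u[1] * v[2] - u[2] * v[1];
  double cy = u[2] * v[0] - u[0] * v[2];
  double cz = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// Marching-tetrahedra surface area (mm^2) and enclosed volume (mm^3) of the
// 0.5 iso-surface of a scalar field sampled at voxel centres. The caller is
// expected to zero-pad the field so the surface is closed. Each cell is split
// into six tetrahedra around the main diagonal.
// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, IntegerVector dim,
                                   NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double iso = 0.5;
  static const int CORN[8][3] = {
    {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}};
  static const int TETS[6][4] = {
    {0,1,3,7},{0,3,2,7},{0,2,6,7},{0,6,4,7},{0,4,5,7},{0,5,1,7}};
  double area = 0.0, vol = 0.0;
  double val[8]; double pos[8][3];
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        bool any = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + CORN[c][0], cy = y + CORN[c][1], cz = z + CORN[c][2];
          val[c] = field[cx + nx * (cy + ny * cz)];
          pos[c][0] = cx * spacing[0]; pos[c][1] = cy * spacing[1]; pos[c][2] = cz * spacing[2];
          if (val[c] > iso) any = true;
        }
        if (!any) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tt = TETS[t];
          double tv[4]; const double *tp[4];
          int inside[4], outside[4]; int ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            tv[k] = val[tt[k]]; tp[k] = pos[tt[k]];
            if (tv[k] > iso) inside[ni++] = k; else outside[no++] = k;
          }
          if (ni == 0) continue;
          if (ni == 4) { vol += tet_vol(tp[0], tp[1], tp[2], tp[3]); continue; }
          double P[4][3]; // interpolated crossing points
          if (ni == 1) {
            int i0 = inside[0];
            for (int k = 0; k < 3; ++k) {
              int j = outside[k];
              double tfr = (iso - tv[i0]) / (tv[j] - tv[i0]);
              for (int m = 0; m < 3; ++m) P[k][m] = tp[i0][m] + tfr * (tp[j][m] - tp[i0][m]);
            }
            area += tri_area(P[0], P[1], P[2]);
            vol += tet_vol(tp[i0], P[0], P[1], P[2]);
          } else if (ni == 3) {
            int o0 = outside[0];
            for (int k = 0; k < 3; ++k) {
              int j = inside[k];
              double tfr = (iso - tv[j]) / (tv[o0] - tv[j]);
              for (int m = 0; m < 3; ++m) P[k][m] = tp[j][m] + tfr * (tp[o0][m] - tp[j][m]);
            }
            area += tri_area(P[0], P[1], P[2]);
            vol += tet_vol(tp[0], tp[1], tp[2], tp[3]) - tet_vol(tp[o0], P[0], P[1], P[2]);
          } else { // 2 in, 2 out -> quad section
            int iA = inside[0], iB = inside[1], iC = outside[0], iD = outside[1];
            double pAC[3], pAD[3], pBC[3], pBD[3];
            double f;
            f = (iso - tv[iA]) / (tv[iC] - tv[iA]);
            for (int m = 0; m < 3; ++m) pAC[m] = tp[iA][m] + f * (tp[iC][m] - tp[iA][m]);
            f = (iso - tv[iA]) / (tv[iD] - tv[iA]);
            for (int m = 0; m < 3; ++m) pAD[m] = tp[iA][m] + f * (tp[iD][m] - tp[iA][m]);
            f = (iso - tv[iB]) / (tv[iC] - tv[iB]);
            for (int m = 0; m < 3; ++m) pBC[m] = tp[iB][m] + f * (tp[iC][m] - tp[iB][m]);
            f = (iso - tv[iB]) / (tv[iD] - tv[iB]);
            for (int m = 0; m < 3; ++m) pBD[m] = tp[iB][m] + f * (tp[iD][m] - tp[iB][m]);
            area += tri_area(pAC, pBC, pAD) + tri_area(pBC, pBD, pAD);
            vol += tet_vol(tp[iA], tp[iB], pAC, pBC);
            vol += tet_vol(tp[iA], pAC, pAD, pBC);
            vol += tet_vol(pAC, pAD, pBC, pBD);
          }
        }
      }
  return NumericVector::create(area, vol);
}

// Largest pairwise Euclidean distance between rows of a coordinate matrix.
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  int n = pts.nrow(), p = pts.ncol();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = pts(i, k) - pts(j, k);
        s += d * d;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
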