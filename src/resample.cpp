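#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Trilinear interpolation at 0-based voxel coordinates; values outside the
// grid are treated as 0 (background air).
static inline double fetch(const double* v, int nx, int ny, int nz,
                           int x, int y, int z) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
  return v[(size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * (size_t)z)];
}

static inline double trilinear(const double* v, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (!R_finite(x) || !R_finite(y) || !R_finite(z)) return 0.0;
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)nx || y >= (double)ny || z >= (double)nz) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = fetch(v, nx, ny, nz, x0, y0, z0) * (1 - fx) +
               fetch(v, nx, ny, nz, x0 + 1, y0, z0) * fx;
  double c10 = fetch(v, nx, ny, nz, x0, y0 + 1, z0) * (1 - fx) +
               fetch(v, nx, ny, nz, x0 + 1, y0 + 1, z0) * fx;
  double c01 = fetch(v, nx, ny, nz, x0, y0, z0 + 1) * (1 - fx) +
               fetch(v, nx, ny, nz, x0 + 1, y0, z0 + 1) * fx;
  double c11 = fetch(v, nx, ny, nz, x0, y0 + 1, z0 + 1) * (1 - fx) +
               fetch(v, nx, ny, nz, x0 + 1, y0 + 1, z0 + 1) * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Sample a volume and the exact spatial derivative of its trilinear
// interpolant at scattered 0-based voxel coordinates. Returns value and the
// three partials in voxel-index units.
// [[Rcpp::export]]
List cpp_sample_points_grad(NumericVector src, IntegerVector dim,
                            NumericVector px, NumericVector py,
                            NumericVector pz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const double* v = REAL(src);
  R_xlen_t n = px.size();
  NumericVector val(n), gx(n), gy(n), gz(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double x = px[i], y = py[i], z = pz[i];
    if (!R_finite(x) || !R_finite(y) || !R_finite(z) ||
        x <= -1.0 || y <= -1.0 || z <= -1.0 ||
        x >= (double)nx || y >= (double)ny || z >= (double)nz) {
      val[i] = gx[i] = gy[i] = gz[i] = 0.0;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
        z0 = (int)std::floor(z);
    double fx = x - x0, fy = y - y0, fz = z - z0;
    double c[2][2][2];
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int cc = 0; cc < 2; ++cc)
          c[a][b][cc] = fetch(v, nx, ny, nz, x0 + a, y0 + b, z0 + cc);
    double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    double dx[2] = {-1.0, 1.0};
    double sv = 0, sgx = 0, sgy = 0, sgz = 0;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int cc = 0; cc < 2; ++cc) {
          double cv = c[a][b][cc];
          sv += cv * wx[a] * wy[b] * wz[cc];
          sgx += cv * dx[a] * wy[b] * wz[cc];
          sgy += cv * wx[a] * dx[b] * wz[cc];
          sgz += cv * wx[a] * wy[b] * dx[cc];
        }
    val[i] = sv; gx[i] = sgx; gy[i] = sgy; gz[i] = sgz;
  }
  return List::create(val, gx, gy, gz);
}

// Sample each volume in `srcs` (3D arrays sharing `dim`) at scattered
// 0-based voxel coordinates.
// [[Rcpp::export]]
List cpp_sample_points(List srcs, IntegerVector dim,
                       NumericVector px, NumericVector py, NumericVector pz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = px.size();
  int nvol = srcs.size();
  List out(nvol);
  for (int m = 0; m < nvol; ++m) {
    NumericVector src = srcs[m];
    const double* v = REAL(src);
    NumericVector res(n);
    for (R_xlen_t i = 0; i < n; ++i)
      res[i] = trilinear(v, nx, ny, nz, px[i], py[i], pz[i]);
    out[m] = res;
  }
  return out;
}

// Resample each source volume onto a destination grid through the 4x4
// voxel-to-voxel map S (0-based dst voxel -> 0-based src voxel).
// [[Rcpp::export]]
List cpp_resample_affine(List srcs, IntegerVector srcDim,
                         NumericMatrix S, IntegerVector dstDim) {
  int nx = srcDim[0], ny = srcDim[1], nz = srcDim[2];
  int mx = dstDim[0], my = dstDim[1], mz = dstDim[2];
  size_t n = (size_t)mx * my * mz;
  int nvol = srcs.size();
  std::vector<const double*> vs(nvol);
  List out(nvol);
  std::vector<double*> os(nvol);
  for (int m = 0; m < nvol; ++m) {
    NumericVector src = srcs[m];
    vs[m] = REAL(src);
    NumericVector res(n);
    res.attr("dim") = dstDim;
    out[m] = res;
    os[m] = REAL((SEXP)out[m]);
  }
  double s00 = S(0,0), s01 = S(0,1), s02 = S(0,2), s03 = S(0,3);
  double s10 = S(1,0), s11 = S(1,1), s12 = S(1,2), s13 = S(1,3);
  double s20 = S(2,0), s21 = S(2,1), s22 = S(2,2), s23 = S(2,3);
  size_t idx = 0;
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i, ++idx) {
        double x = s00 * i + s01 * j + s02 * k + s03;
        double y = s10 * i + s11 * j + s12 * k + s13;
        double z = s20 * i + s21 * j + s22 * k + s23;
        for (int m = 0; m < nvol; ++m)
          os[m][idx] = trilinear(vs[m], nx, ny, nz, x, y, z);
      }
  return out;
}

// Separable Gaussian smoothing with zero padding; kernel truncated at
// 3.5 sigma and normalized to unit sum.
static void smooth_axis(std::vector<double>& a, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(3.5 * sigma);
  if (r < 1) return;
  std::vector<double> ker(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    ker[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += ker[i + r];
  }
  for (double& k : ker) k /= s;
  int n[3] = {nx, ny, nz};
  size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  size_t st = stride[axis];
  int len = n[axis];
  std::vector<double> line(len);
  // iterate over all lines along `axis`
  int o1 = (axis == 0) ? 1 : 0;
  int o2 = (axis == 2) ? 1 : 2;
  for (int j2 = 0; j2 < n[o2]; ++j2)
    for (int j1 = 0; j1 < n[o1]; ++j1) {
      size_t base = stride[o1] * j1 + stride[o2] * j2;
      for (int i = 0; i < len; ++i) line[i] = a[base + st * i];
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
        for (int u = lo; u <= hi; ++u) acc += line[u] * ker[u - i + r];
        a[base + st * i] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector src, IntegerVector dim,
                               NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(REAL(src), REAL(src) + (size_t)nx * ny * nz);
  smooth_axis(a, nx, ny, nz, 0, sigma_vox[0]);
  smooth_axis(a, nx, ny, nz, 1, sigma_vox[1]);
  smooth_axis(a, nx, ny, nz, 2, sigma_vox[2]);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// 6-connected component labelling of a binary mask; labels start at 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  const int* m = LOGICAL(mask);
  std::vector<size_t> stack;
  int next = 0;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (size_t s = 0; s < n; ++s) {
    if (m[s] != 1 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t c = stack.back();
      stack.pop_back();
      int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        size_t cc = (size_t)xx + (size_t)nx * ((size_t)yy + (size_t)ny * zz);
        if (m[cc] == 1 && lab[cc] == 0) {
          lab[cc] = next;
          stack.push_back(cc);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Fill interior cavities: background connected to the volume border stays
// background, everything else becomes foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  std::vector<char> outside(n, 0);
  std::vector<size_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && z != 0 && x != nx - 1 && y != ny - 1 &&
            z != nz - 1)
          continue;
        size_t c = (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
        if (m[c] != 1 && !outside[c]) {
          outside[c] = 1;
          stack.push_back(c);
        }
      }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  while (!stack.empty()) {
    size_t c = stack.back();
    stack.pop_back();
    int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
    for (int d = 0; d < 6; ++d) {
      int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      size_t cc = (size_t)xx + (size_t)nx * ((size_t)yy + (size_t)ny * zz);
      if (m[cc] != 1 && !outside[cc]) {
        outside[cc] = 1;
        stack.push_back(cc);
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (m[i] == 1) || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Binary erosion with the 6-neighbourhood structuring element, `iters` times;
// voxels outside the grid count as background.
// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dim, int iters) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (size_t i = 0; i < n; ++i) cur[i] = LOGICAL(mask)[i] == 1;
  for (int it = 0; it < iters; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          size_t c = (size_t)x + (size_t)nx * ((size_t)y + (size_t)ny * z);
          char keep = cur[c];
          if (keep) {
            keep = x > 0 && x < nx - 1 && y > 0 && y < ny - 1 && z > 0 &&
                   z < nz - 1;
            if (keep)
              keep = cur[c - 1] && cur[c + 1] && cur[c - nx] && cur[c + nx] &&
                     cur[c - (size_t)nx * ny] && cur[c + (size_t)nx * ny];
          }
          nxt[c] = keep;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dim;
  return out;
}
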