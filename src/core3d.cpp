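#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Voxel grids arrive as R arrays in column-major order: index
// (i,j,k) -> i + nx*(j + ny*k), 0-based here.  All kernels assume
// isotropic voxels; physical scaling happens on the R side.

static inline int reflect(int i, int n) {
  // reflect-101 style boundary (a b c | b a) degenerates safely for n==1
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector v, IntegerVector dim, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = k / 2;
  NumericVector out(v.size());
  std::vector<double> buf;
  buf.reserve((size_t)k * k * k);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        buf.clear();
        for (int dz = -h; dz <= h; ++dz) {
          const int zz = reflect(z + dz, nz);
          for (int dy = -h; dy <= h; ++dy) {
            const int yy = reflect(y + dy, ny);
            for (int dx = -h; dx <= h; ++dx) {
              const int xx = reflect(x + dx, nx);
              buf.push_back(v[xx + (size_t)nx * (yy + (size_t)ny * zz)]);
            }
          }
        }
        const size_t m = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + m, buf.end());
        out[x + (size_t)nx * (y + (size_t)ny * z)] = buf[m];
      }
  return out;
}

static void blur_axis(std::vector<double>& a, int nx, int ny, int nz,
                      const std::vector<double>& ker, int axis) {
  const int h = (int)ker.size() / 2;
  std::vector<double> out(a.size());
  const int n[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int na = n[axis];
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const int idx3[3] = {x, y, z};
        double s = 0.0;
        for (int d = -h; d <= h; ++d) {
          int p = reflect(idx3[axis] + d, na);
          size_t off = (size_t)x * stride[0] + (size_t)y * stride[1] +
                       (size_t)z * stride[2] +
                       ((size_t)p - (size_t)idx3[axis]) * stride[axis];
          s += ker[d + h] * a[off];
        }
        out[(size_t)x + (size_t)nx * (y + (size_t)ny * z)] = s;
      }
  a.swap(out);
}

// Separable Gaussian; when normalized each 1-D kernel sums to 1,
// otherwise raw exp(-i^2 / (2 sigma^2)) weights are used.
// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector v, IntegerVector dim, double sigma,
                          bool normalized) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  int h = (int)std::ceil(4.0 * sigma);
  if (h < 1) h = 1;
  std::vector<double> ker(2 * h + 1);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    ker[i + h] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += ker[i + h];
  }
  if (normalized)
    for (auto& w : ker) w /= s;
  std::vector<double> a(v.begin(), v.end());
  for (int ax = 0; ax < 3; ++ax) blur_axis(a, nx, ny, nz, ker, ax);
  return NumericVector(a.begin(), a.end());
}

// Intensity-domain mean-shift smoothing: each voxel's value moves to the
// mean of neighbourhood intensities within +/- bandwidth of the current
// value, iterated until the shift drops below tol (absolute) or maxit.
// [[Rcpp::export]]
NumericVector cpp_meanshift3d(NumericVector v, IntegerVector dim, int window,
                              double bandwidth, int maxit, double tol) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = window / 2;
  NumericVector out(v.size());
  std::vector<double> nb;
  nb.reserve((size_t)window * window * window);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        nb.clear();
        for (int dz = -h; dz <= h; ++dz) {
          const int zz = reflect(z + dz, nz);
          for (int dy = -h; dy <= h; ++dy) {
            const int yy = reflect(y + dy, ny);
            for (int dx = -h; dx <= h; ++dx) {
              const int xx = reflect(x + dx, nx);
              nb.push_back(v[xx + (size_t)nx * (yy + (size_t)ny * zz)]);
            }
          }
        }
        double m = v[x + (size_t)nx * (y + (size_t)ny * z)];
        for (int it = 0; it < maxit; ++it) {
          double s = 0.0;
          int c = 0;
          for (double u : nb)
            if (std::fabs(u - m) <= bandwidth) { s += u; ++c; }
          if (c == 0) break;
          const double m2 = s / c;
          const double shift = std::fabs(m2 - m);
          m = m2;
          if (shift < tol) break;
        }
        out[x + (size_t)nx * (y + (size_t)ny * z)] = m;
      }
  return out;
}

// Felzenszwalb & Huttenlocher 1-D squared distance transform
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& vv, std::vector<double>& zz, int n) {
  int k = 0;
  vv[0] = 0;
  zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double sq;
    while (true) {
      sq = ((f[q] + (double)q * q) - (f[vv[k]] + (double)vv[k] * vv[k])) /
           (2.0 * q - 2.0 * vv[k]);
      if (sq <= zz[k]) { --k; } else break;
    }
    ++k;
    vv[k] = q;
    zz[k] = sq;
    zz[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zz[k + 1] < q) ++k;
    const double dq = q - vv[k];
    d[q] = dq * dq + f[vv[k]];
  }
}

// Squared Euclidean distance (voxel units) to the nearest TRUE voxel.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector feature, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e18;
  std::vector<double> g(feature.size());
  for (R_xlen_t i = 0; i < feature.size(); ++i)
    g[i] = feature[i] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), zz(nmax + 1);
  std::vector<int> vv(nmax);
  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(f, d, vv, zz, nx);
      for (int x = 0; x < nx; ++x) g[x + (size_t)nx * (y + (size_t)ny * z)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(f, d, vv, zz, ny);
      for (int y = 0; y < ny; ++y) g[x + (size_t)nx * (y + (size_t)ny * z)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(f, d, vv, zz, nz);
      for (int z = 0; z < nz; ++z) g[x + (size_t)nx * (y + (size_t)ny * z)] = d[z];
    }
  NumericVector out(g.begin(), g.end());
  return out;
}

// Connected-component labelling, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int man = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && man > 1) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  int next = 0;
  std::vector<size_t> stack;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back((size_t)s);
    lab[s] = next;
    while (!stack.empty()) {
      const size_t p = stack.back();
      stack.pop_back();
      const int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((size_t)nx * ny));
      for (size_t q = 0; q < ox.size(); ++q) {
        const int xx = x + ox[q], yy = y + oy[q], zz2 = z + oz[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz2 < 0 || zz2 >= nz) continue;
        const size_t pp = xx + (size_t)nx * (yy + (size_t)ny * zz2);
        if (mask[pp] && !lab[pp]) {
          lab[pp] = next;
          stack.push_back(pp);
        }
      }
    }
  }
  return lab;
}

// Largest-inscribed-sphere local thickness (sphere painting), classic
// distance-transform convention: the sphere centred at q has radius
// d(q), the Euclidean distance to the nearest background voxel centre,
// and every structure voxel it covers is at least 2 d(q) thick.  The
// half-voxel overshoot at axis-aligned surfaces compensates the
// undershoot at diagonal ones; an isolated voxel reads 2 voxels.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector bg(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) bg[i] = !mask[i];
  NumericVector d2 = cpp_edt_sq(bg, dim);
  NumericVector th(mask.size(), 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const size_t p = x + (size_t)nx * (y + (size_t)ny * z);
        if (!mask[p]) continue;
        const double dC = std::sqrt(d2[p]);
        const double r = dC;
        const double t = 2.0 * r;
        const int ir = (int)std::floor(r);
        for (int dz = -ir; dz <= ir; ++dz)
          for (int dy = -ir; dy <= ir; ++dy)
            for (int dx = -ir; dx <= ir; ++dx) {
              if ((double)(dx * dx + dy * dy + dz * dz) > r * r) continue;
              const int xx = x + dx, yy = y + dy, zz2 = z + dz;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz2 < 0 || zz2 >= nz)
                continue;
              const size_t q = xx + (size_t)nx * (yy + (size_t)ny * zz2);
              if (mask[q] && th[q] < t) th[q] = t;
            }
      }
  return th;
}

// Pull-back affine resampling: for output voxel index o (0-based),
// source index s = A o + t; trilinear or nearest-neighbour lookup.
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector v, IntegerVector dim,
                                  NumericMatrix A, NumericVector t,
                                  IntegerVector outdim, bool nearest,
                                  double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = outdim[0], my = outdim[1], mz = outdim[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  for (int z = 0; z < mz; ++z)
    for (int y = 0; y < my; ++y)
      for (int x = 0; x < mx; ++x) {
        const double sx = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t[0];
        const double sy = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t[1];
        const double sz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t[2];
        double val = fill;
        if (nearest) {
          const int ix = (int)std::lround(sx), iy = (int)std::lround(sy),
                    iz = (int)std::lround(sz);
          if (ix >= 0 && ix < nx && iy >= 0 && iy < ny && iz >= 0 && iz < nz)
            val = v[ix + (size_t)nx * (iy + (size_t)ny * iz)];
        } else {
          const int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy),
                    z0 = (int)std::floor(sz);
          if (x0 >= -1 && x0 < nx && y0 >= -1 && y0 < ny && z0 >= -1 && z0 < nz) {
            const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
            double acc = 0.0, wsum = 0.0;
            bool inside = true;
            for (int c = 0; c < 8; ++c) {
              const int ix = x0 + (c & 1), iy = y0 + ((c >> 1) & 1),
                        iz = z0 + ((c >> 2) & 1);
              const double w = ((c & 1) ? fx : 1 - fx) *
                               (((c >> 1) & 1) ? fy : 1 - fy) *
                               (((c >> 2) & 1) ? fz : 1 - fz);
              if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
                if (w > 1e-12) inside = false;
                continue;
              }
              acc += w * v[ix + (size_t)nx * (iy + (size_t)ny * iz)];
              wsum += w;
            }
            if (inside && wsum > 0) val = acc / wsum;
          }
        }
        out[x + (size_t)mx * (y + (size_t)my * z)] = val;
      }
  return out;
}

// Paint a capsule (cylinder with spherical caps) of given radius (voxel
// units) into an integer label grid, converting voxels whose current
// label equals `from` to `to`, and recording the capsule axis in the
// orientation arrays for the voxels painted.  Returns number painted.
// [[Rcpp::export]]
int cpp_paint_capsule(IntegerVector lab, IntegerVector dim,
                      NumericVector p0, NumericVector p1, double radius,
                      int from, int to,
                      NumericVector ox, NumericVector oy, NumericVector oz,
                      NumericVector axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double lo[3] = {std::min(p0[0], p1[0]) - radius,
                        std::min(p0[1], p1[1]) - radius,
                        std::min(p0[2], p1[2]) - radius};
  const double hi[3] = {std::max(p0[0], p1[0]) + radius,
                        std::max(p0[1], p1[1]) + radius,
                        std::max(p0[2], p1[2]) + radius};
  const int x0 = std::max(0, (int)std::floor(lo[0])),
            x1 = std::min(nx - 1, (int)std::ceil(hi[0]));
  const int y0 = std::max(0, (int)std::floor(lo[1])),
            y1 = std::min(ny - 1, (int)std::ceil(hi[1]));
  const int z0 = std::max(0, (int)std::floor(lo[2])),
            z1 = std::min(nz - 1, (int)std::ceil(hi[2]));
  const double ux = p1[0] - p0[0], uy = p1[1] - p0[1], uz = p1[2] - p0[2];
  const double L2 = ux * ux + uy * uy + uz * uz;
  const double r2 = radius * radius;
  int painted = 0;
  for (int z = z0; z <= z1; ++z)
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double wx = x - p0[0], wy = y - p0[1], wz = z - p0[2];
        double s = L2 > 0 ? (wx * ux + wy * uy + wz * uz) / L2 : 0.0;
        if (s < 0) s = 0; else if (s > 1) s = 1;
        const double dx = wx - s * ux, dy = wy - s * uy, dz = wz - s * uz;
        if (dx * dx + dy * dy + dz * dz > r2) continue;
        const size_t p = x + (size_t)nx * (y + (size_t)ny * z);
        if (lab[p] != from) continue;
        lab[p] = to;
        ox[p] = axis[0];
        oy[p] = axis[1];
        oz[p] = axis[2];
        ++painted;
      }
  return painted;
}
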