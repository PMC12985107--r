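#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

// 3D median filter, odd cubic kernel, replicate borders.
// [[Rcpp::export]]
NumericVector cpp_median_filter3(NumericVector vol, IntegerVector dim, int k) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int h = k / 2, kk = k * k * k;
  NumericVector out(vol.size());
  std::vector<double> buf(kk);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int m = 0;
        for (int dz = -h; dz <= h; ++dz) {
          int zz = clampi(z + dz, 0, nz - 1);
          for (int dy = -h; dy <= h; ++dy) {
            int yy = clampi(y + dy, 0, ny - 1);
            const double *col = &vol[(size_t)zz * nx * ny + (size_t)yy * nx];
            for (int dx = -h; dx <= h; ++dx)
              buf[m++] = col[clampi(x + dx, 0, nx - 1)];
          }
        }
        std::nth_element(buf.begin(), buf.begin() + kk / 2, buf.begin() + kk);
        out[(size_t)z * nx * ny + (size_t)y * nx + x] = buf[kk / 2];
      }
    }
  }
  return out;
}

// Trilinear interpolation of a 3D grid at the Cartesian product of query
// coordinates (1-based continuous index space, clamped to the grid).
// [[Rcpp::export]]
NumericVector cpp_trilinear_grid(NumericVector src, IntegerVector dim,
                                 NumericVector xi, NumericVector yi,
                                 NumericVector zi) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = xi.size(), oy = yi.size(), oz = zi.size();
  NumericVector out((size_t)ox * oy * oz);
  std::vector<int> x0(ox), y0(oy), z0(oz);
  std::vector<double> fx(ox), fy(oy), fz(oz);
  auto prep = [](NumericVector q, int n, std::vector<int> &i0,
                 std::vector<double> &fr) {
    for (int j = 0; j < (int)i0.size(); ++j) {
      double v = q[j];
      if (v < 1.0) v = 1.0;
      if (v > n) v = n;
      int i = (int)std::floor(v) - 1;      // 0-based lower node
      if (i > n - 2) i = n - 2;
      if (i < 0) i = 0;
      i0[j] = i;
      fr[j] = n == 1 ? 0.0 : v - 1.0 - i;
    }
  };
  prep(xi, nx, x0, fx);
  prep(yi, ny, y0, fy);
  prep(zi, nz, z0, fz);
  size_t o = 0;
  for (int z = 0; z < oz; ++z) {
    const size_t zA = (size_t)z0[z] * nx * ny;
    const size_t zB = nz == 1 ? zA : zA + (size_t)nx * ny;
    const double wz = fz[z];
    for (int y = 0; y < oy; ++y) {
      const size_t yA = (size_t)y0[y] * nx;
      const size_t yB = ny == 1 ? yA : yA + nx;
      const double wy = fy[y];
      for (int x = 0; x < ox; ++x, ++o) {
        const int xA = x0[x];
        const int xB = nx == 1 ? xA : xA + 1;
        const double wx = fx[x];
        const double c00 = src[zA + yA + xA] * (1 - wx) + src[zA + yA + xB] * wx;
        const double c10 = src[zA + yB + xA] * (1 - wx) + src[zA + yB + xB] * wx;
        const double c01 = src[zB + yA + xA] * (1 - wx) + src[zB + yA + xB] * wx;
        const double c11 = src[zB + yB + xA] * (1 - wx) + src[zB + yB + xB] * wx;
        out[o] = (c00 * (1 - wy) + c10 * wy) * (1 - wz) +
                 (c01 * (1 - wy) + c11 * wy) * wz;
      }
    }
  }
  return out;
}

// 6-connected component labelling of a logical 3D mask (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<size_t> stack;
  int cur = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t p = stack.back();
      stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / ((size_t)nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int d = 0; d < 6; ++d) {
        int xx = x + dx[d], yy = y + dy[d], zz = z + dz[d];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        size_t q = (size_t)zz * nx * ny + (size_t)yy * nx + xx;
        if (mask[q] && !lab[q]) {
          lab[q] = cur;
          stack.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Separable convolution along one axis (0, 1 or 2), replicate borders.
// Used for the Gaussian point-spread surrogate.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dim,
                                NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int kl = kernel.size(), h = kl / 2;
  NumericVector out(vol.size());
  const int nax[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  const int na = nax[axis];
  const size_t st = stride[axis];
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int idxa[3] = {x, y, z};
        if (idxa[axis] != 0) continue;  // iterate lines once
        size_t base = (size_t)z * nx * ny + (size_t)y * nx + x;
        for (int a = 0; a < na; ++a) {
          double acc = 0;
          for (int j = 0; j < kl; ++j) {
            int p = clampi(a + j - h, 0, na - 1);
            acc += kernel[j] * vol[base + (size_t)p * st];
          }
          out[base + (size_t)a * st] = acc;
        }
      }
    }
  }
  return out;
}
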