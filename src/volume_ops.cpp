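#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Index helper for column-major 3D arrays.
static inline R_xlen_t IX(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

// Convolve along one axis with an odd symmetric kernel, mirror boundary.
static void conv_axis(std::vector<double> &v, int nx, int ny, int nz,
                      const std::vector<double> &k, int axis) {
  int r = ((int)k.size() - 1) / 2;
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  std::vector<double> line(len), out(len);
  int o0 = axis == 0 ? 1 : (axis == 1 ? 0 : 0);
  int o1 = axis == 0 ? 2 : (axis == 1 ? 2 : 1);
  for (int a = 0; a < n[o0]; ++a) {
    for (int b = 0; b < n[o1]; ++b) {
      for (int i = 0; i < len; ++i) {
        int c[3];
        c[axis] = i; c[o0] = a; c[o1] = b;
        line[i] = v[IX(c[0], c[1], c[2], nx, ny)];
      }
      for (int i = 0; i < len; ++i) {
        double s = 0.0;
        for (int j = -r; j <= r; ++j) {
          int p = i + j;
          if (p < 0) p = -p;              // mirror
          if (p >= len) p = 2 * len - 2 - p;
          if (p < 0) p = 0;               // degenerate len == 1
          s += k[j + r] * line[p];
        }
        out[i] = s;
      }
      for (int i = 0; i < len; ++i) {
        int c[3];
        c[axis] = i; c[o0] = a; c[o1] = b;
        v[IX(c[0], c[1], c[2], nx, ny)] = out[i];
      }
    }
  }
}

// Separable truncated Gaussian smoothing. sigma and radius per axis (voxels).
// Kernel renormalized to unit sum, so constants are preserved exactly.
// [[Rcpp::export(name = ".cpp_gaussian_smooth")]]
NumericVector cpp_gaussian_smooth(NumericVector vol, IntegerVector dim,
                                  NumericVector sigma, IntegerVector radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int ax = 0; ax < 3; ++ax) {
    int r = radius[ax];
    double s = sigma[ax];
    if (r <= 0 || s <= 0) continue;
    std::vector<double> k(2 * r + 1);
    double tot = 0.0;
    for (int j = -r; j <= r; ++j) {
      k[j + r] = std::exp(-0.5 * (double)j * j / (s * s));
      tot += k[j + r];
    }
    for (double &w : k) w /= tot;
    conv_axis(v, nx, ny, nz, k, ax);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---- cubic B-spline prefilter (Unser), mirror boundary -------------------

static void prefilter_line(std::vector<double> &c) {
  const double z = std::sqrt(3.0) - 2.0;  // pole of the cubic B-spline
  const double lambda = 6.0;
  int n = (int)c.size();
  if (n == 1) return;
  for (int i = 0; i < n; ++i) c[i] *= lambda;
  // causal init: truncated sum over the mirrored signal
  double zn = z, sum = c[0];
  int horizon = std::min(n, (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z))));
  for (int i = 1; i < horizon; ++i) { sum += zn * c[i]; zn *= z; }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i] += z * c[i - 1];
  // anticausal init
  c[n - 1] = (z / (z * z - 1.0)) * (z * c[n - 2] + c[n - 1]);
  for (int i = n - 2; i >= 0; --i) c[i] = z * (c[i + 1] - c[i]);
}

static void prefilter_axis(std::vector<double> &v, int nx, int ny, int nz, int axis) {
  int n[3] = {nx, ny, nz};
  int len = n[axis];
  int o0 = axis == 0 ? 1 : 0;
  int o1 = axis == 2 ? 1 : 2;
  std::vector<double> line(len);
  for (int a = 0; a < n[o0]; ++a)
    for (int b = 0; b < n[o1]; ++b) {
      for (int i = 0; i < len; ++i) {
        int c[3]; c[axis] = i; c[o0] = a; c[o1] = b;
        line[i] = v[IX(c[0], c[1], c[2], nx, ny)];
      }
      prefilter_line(line);
      for (int i = 0; i < len; ++i) {
        int c[3]; c[axis] = i; c[o0] = a; c[o1] = b;
        v[IX(c[0], c[1], c[2], nx, ny)] = line[i];
      }
    }
}

static inline int mirror(int p, int n) {
  if (n == 1) return 0;
  while (p < 0 || p >= n) {
    if (p < 0) p = -p;
    if (p >= n) p = 2 * n - 2 - p;
  }
  return p;
}

static inline void bspline_weights(double t, double w[4]) {
  // cubic B-spline basis at offsets -1..2 from floor(t); t in [0,1)
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// Resample a volume to a new spacing. order: 0 nearest-neighbour, 1 trilinear,
// 3 cubic B-spline (with prefilter). Grid is corner/index aligned: output
// index j maps to input continuous index j * out_spacing / in_spacing.
// [[Rcpp::export(name = ".cpp_resample")]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dim,
                           NumericVector in_sp, NumericVector out_sp,
                           IntegerVector out_dim, int order) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  if (order == 3) {
    prefilter_axis(v, nx, ny, nz, 0);
    prefilter_axis(v, nx, ny, nz, 1);
    prefilter_axis(v, nx, ny, nz, 2);
  }
  NumericVector out((R_xlen_t)ox * oy * oz);
  double rx = out_sp[0] / in_sp[0], ry = out_sp[1] / in_sp[1], rz = out_sp[2] / in_sp[2];
  for (int k = 0; k < oz; ++k) {
    double zc = k * rz;
    for (int j = 0; j < oy; ++j) {
      double yc = j * ry;
      for (int i = 0; i < ox; ++i) {
        double xc = i * rx;
        double val = 0.0;
        if (order == 0) {
          int xi = mirror((int)std::lround(xc), nx);
          int yi = mirror((int)std::lround(yc), ny);
          int zi = mirror((int)std::lround(zc), nz);
          val = v[IX(xi, yi, zi, nx, ny)];
        } else if (order == 1) {
          int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc), z0 = (int)std::floor(zc);
          double fx = xc - x0, fy = yc - y0, fz = zc - z0;
          for (int dz = 0; dz <= 1; ++dz)
            for (int dy = 0; dy <= 1; ++dy)
              for (int dx = 0; dx <= 1; ++dx) {
                double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                val += w * v[IX(mirror(x0 + dx, nx), mirror(y0 + dy, ny),
                                mirror(z0 + dz, nz), nx, ny)];
              }
        } else {
          int x0 = (int)std::floor(xc), y0 = (int)std::floor(yc), z0 = (int)std::floor(zc);
          double wx[4], wy[4], wz[4];
          bspline_weights(xc - x0, wx);
          bspline_weights(yc - y0, wy);
          bspline_weights(zc - z0, wz);
          for (int dz = 0; dz < 4; ++dz)
            for (int dy = 0; dy < 4; ++dy)
              for (int dx = 0; dx < 4; ++dx)
                val += wx[dx] * wy[dy] * wz[dz] *
                       v[IX(mirror(x0 - 1 + dx, nx), mirror(y0 - 1 + dy, ny),
                            mirror(z0 - 1 + dz, nz), nx, ny)];
        }
        out[IX(i, j, k, ox, oy)] = val;
      }
    }
  }
  out.attr("dim") = out_dim;
  return out;
}
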