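#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discretized image conventions: integer gray levels 1..Ng inside the ROI,
// 0 outside. All matrices are accumulated over the full 3D neighbourhood
// (13 unique direction vectors for GLCM/GLRLM, 26-connectivity for
// GLSZM/GLDM/NGTDM) at distance 1, as the standard 3D radiomics extractors do.

static inline R_xlen_t IX(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

static const int DIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1}, {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Symmetric GLCM per direction: Ng x Ng x 13 count array.
// [[Rcpp::export(name = ".cpp_glcm")]]
NumericVector cpp_glcm(IntegerVector img, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)ng * ng * 13);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = img[IX(x, y, z, nx, ny)];
        if (g <= 0) continue;
        for (int d = 0; d < 13; ++d) {
          int x2 = x + DIR13[d][0], y2 = y + DIR13[d][1], z2 = z + DIR13[d][2];
          if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
          int g2 = img[IX(x2, y2, z2, nx, ny)];
          if (g2 <= 0) continue;
          out[(R_xlen_t)(g - 1) + (R_xlen_t)ng * ((g2 - 1) + (R_xlen_t)ng * d)] += 1.0;
          out[(R_xlen_t)(g2 - 1) + (R_xlen_t)ng * ((g - 1) + (R_xlen_t)ng * d)] += 1.0;
        }
      }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// Run-length matrix per direction: Ng x maxlen x 13 counts.
// [[Rcpp::export(name = ".cpp_glrlm")]]
NumericVector cpp_glrlm(IntegerVector img, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int maxlen = std::max(nx, std::max(ny, nz));
  NumericVector out((R_xlen_t)ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    int dx = DIR13[d][0], dy = DIR13[d][1], dz = DIR13[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g = img[IX(x, y, z, nx, ny)];
          if (g <= 0) continue;
          // run start: predecessor out of bounds, outside ROI, or different level
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              img[IX(px, py, pz, nx, ny)] == g)
            continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 img[IX(cx, cy, cz, nx, ny)] == g) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          if (len > maxlen) len = maxlen;
          out[(R_xlen_t)(g - 1) + (R_xlen_t)ng * ((len - 1) + (R_xlen_t)maxlen * d)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// Size-zone list: 26-connected components of equal gray level.
// Returns a 2-column matrix (level, size).
// [[Rcpp::export(name = ".cpp_glszm_zones")]]
IntegerMatrix cpp_glszm_zones(IntegerVector img, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> levels, sizes;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i0 = IX(x, y, z, nx, ny);
        int g = img[i0];
        if (g <= 0 || seen[i0]) continue;
        int size = 0;
        stack.clear();
        stack.push_back(i0);
        seen[i0] = 1;
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          ++size;
          int cz = (int)(cur / ((R_xlen_t)nx * ny));
          int rem = (int)(cur - (R_xlen_t)cz * nx * ny);
          int cy = rem / nx, cx = rem % nx;
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                if (!dx && !dy && !dz) continue;
                int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
                if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                  continue;
                R_xlen_t i2 = IX(x2, y2, z2, nx, ny);
                if (!seen[i2] && img[i2] == g) {
                  seen[i2] = 1;
                  stack.push_back(i2);
                }
              }
        }
        levels.push_back(g);
        sizes.push_back(size);
      }
  IntegerMatrix out((int)levels.size(), 2);
  for (int i = 0; i < (int)levels.size(); ++i) {
    out(i, 0) = levels[i];
    out(i, 1) = sizes[i];
  }
  return out;
}

// Dependence matrix: counts of (gray level, 1 + #26-neighbours with equal
// level). The centre voxel counts itself, so dependence sizes start at 1.
// [[Rcpp::export(name = ".cpp_gldm")]]
NumericMatrix cpp_gldm(IntegerVector img, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27);  // dependence size 1..27
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = img[IX(x, y, z, nx, ny)];
        if (g <= 0) continue;
        int dep = 1;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              if (img[IX(x2, y2, z2, nx, ny)] == g) ++dep;
            }
        out(g - 1, dep - 1) += 1.0;
      }
  return out;
}

// NGTDM accumulators: per level, count n_i and coarseness sum
// s_i = sum over voxels of |level - mean of in-ROI neighbours|.
// [[Rcpp::export(name = ".cpp_ngtdm")]]
NumericMatrix cpp_ngtdm(IntegerVector img, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);  // col 0: n_i, col 1: s_i
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = img[IX(x, y, z, nx, ny)];
        if (g <= 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              int g2 = img[IX(x2, y2, z2, nx, ny)];
              if (g2 > 0) { sum += g2; ++cnt; }
            }
        if (cnt == 0) continue;
        out(g - 1, 0) += 1.0;
        out(g - 1, 1) += std::fabs((double)g - sum / cnt);
      }
  return out;
}

// Surface voxels (6-connectivity exposure) and exposed-face count.
// Returns list(coords = m x 3 integer matrix of 0-based voxel coords,
//              faces = exposed face count).
// [[Rcpp::export(name = ".cpp_surface")]]
List cpp_surface(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int D6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  std::vector<int> xs, ys, zs;
  std::vector<int> fc;  // exposed faces per axis pair: 0 x, 1 y, 2 z
  long faces_x = 0, faces_y = 0, faces_z = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[IX(x, y, z, nx, ny)]) continue;
        bool surf = false;
        for (int d = 0; d < 6; ++d) {
          int x2 = x + D6[d][0], y2 = y + D6[d][1], z2 = z + D6[d][2];
          bool outside = (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                          z2 < 0 || z2 >= nz) || !mask[IX(x2, y2, z2, nx, ny)];
          if (outside) {
            surf = true;
            if (d < 2) ++faces_x; else if (d < 4) ++faces_y; else ++faces_z;
          }
        }
        if (surf) { xs.push_back(x); ys.push_back(y); zs.push_back(z); }
      }
  IntegerMatrix coords((int)xs.size(), 3);
  for (int i = 0; i < (int)xs.size(); ++i) {
    coords(i, 0) = xs[i]; coords(i, 1) = ys[i]; coords(i, 2) = zs[i];
  }
  return List::create(_["coords"] = coords,
                      _["faces"] = NumericVector::create((double)faces_x,
                                                         (double)faces_y,
                                                         (double)faces_z));
}

// Maximum pairwise Euclidean distance among points (rows of m x 3 matrix of
// physical coordinates). Optional grouping column for per-slice 2D diameters.
// [[Rcpp::export(name = ".cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericMatrix pts, IntegerVector group) {
  int m = pts.nrow();
  bool grouped = group.size() == m;
  double best = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      if (grouped && group[i] != group[j]) continue;
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d > best) best = d;
    }
  return std::sqrt(best);
}
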