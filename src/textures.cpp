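#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D direction offsets (half of the 26-neighbourhood; the other
// half is covered by symmetry).  Order is fixed: it defines the direction
// index used when features are averaged over directions.
static const int DIRS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int vox(int x, int y, int z, int X, int Y) {
  return x + X * (y + Y * z);
}

// g: integer gray levels on the full grid, 0 outside the mask, 1..Ng inside.
// Returns a list of 13 symmetric Ng x Ng co-occurrence count matrices
// (distance 1, one per direction).
// [[Rcpp::export]]
List cpp_glcm(IntegerVector g, IntegerVector dims, int ng) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  List out(13);
  for (int d = 0; d < 13; ++d) {
    IntegerMatrix P(ng, ng);
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
      int gi = g[vox(x, y, z, X, Y)];
      if (gi == 0) continue;
      int nx = x + dx, ny = y + dy, nz = z + dz;
      if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
      int gj = g[vox(nx, ny, nz, X, Y)];
      if (gj == 0) continue;
      P(gi - 1, gj - 1) += 1;
      P(gj - 1, gi - 1) += 1;
    }
    out[d] = P;
  }
  return out;
}

// Run-length matrices: one Ng x Lmax count matrix per direction.  A run is a
// maximal collinear streak of in-mask voxels sharing a gray level.
// [[Rcpp::export]]
List cpp_glrlm(IntegerVector g, IntegerVector dims, int ng) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int lmax = X + Y + Z;  // safe upper bound on run length
  List out(13);
  for (int d = 0; d < 13; ++d) {
    IntegerMatrix P(ng, lmax);
    int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
      int gi = g[vox(x, y, z, X, Y)];
      if (gi == 0) continue;
      // run starts here only if the predecessor is not part of the same run
      int px = x - dx, py = y - dy, pz = z - dz;
      if (px >= 0 && py >= 0 && pz >= 0 && px < X && py < Y && pz < Z &&
          g[vox(px, py, pz, X, Y)] == gi) continue;
      int len = 1;
      int cx = x + dx, cy = y + dy, cz = z + dz;
      while (cx >= 0 && cy >= 0 && cz >= 0 && cx < X && cy < Y && cz < Z &&
             g[vox(cx, cy, cz, X, Y)] == gi) {
        ++len; cx += dx; cy += dy; cz += dz;
      }
      P(gi - 1, len - 1) += 1;
    }
    out[d] = P;
  }
  return out;
}

// Size-zone: 26-connected components of equal gray level.  Returns a
// two-column matrix (gray level, zone size), one row per zone.
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector g, IntegerVector dims) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int n = X * Y * Z;
  std::vector<char> seen(n, 0);
  std::vector<int> zg, zs, stack;
  for (int i = 0; i < n; ++i) {
    if (g[i] == 0 || seen[i]) continue;
    int gl = g[i], size = 0;
    stack.clear(); stack.push_back(i); seen[i] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cz = cur / (X * Y), rem = cur % (X * Y);
      int cy = rem / X, cx = rem % X;
      for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int nx = cx + dx, ny = cy + dy, nz = cz + dz;
        if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
        int j = vox(nx, ny, nz, X, Y);
        if (!seen[j] && g[j] == gl) { seen[j] = 1; stack.push_back(j); }
      }
    }
    zg.push_back(gl); zs.push_back(size);
  }
  IntegerMatrix out(zg.size(), 2);
  for (size_t k = 0; k < zg.size(); ++k) { out(k, 0) = zg[k]; out(k, 1) = zs[k]; }
  return out;
}

// Dependence matrix: for each in-mask voxel, the number of 26-neighbours
// (in mask) whose gray level differs by at most alpha.  Column index is the
// dependence count + 1, so columns run 1..27.
// [[Rcpp::export]]
IntegerMatrix cpp_gldm(IntegerVector g, IntegerVector dims, int ng, int alpha) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  IntegerMatrix P(ng, 27);
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    int gi = g[vox(x, y, z, X, Y)];
    if (gi == 0) continue;
    int dep = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int nx = x + dx, ny = y + dy, nz = z + dz;
      if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
      int gj = g[vox(nx, ny, nz, X, Y)];
      if (gj != 0 && std::abs(gj - gi) <= alpha) ++dep;
    }
    P(gi - 1, dep) += 1;
  }
  return P;
}

// Neighbourhood gray-tone difference: per gray level i, the voxel count n_i
// and the summed absolute difference s_i between the level and the mean of
// the in-mask 26-neighbourhood.  Voxels with no in-mask neighbour are skipped.
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector g, IntegerVector dims, int ng) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  NumericMatrix out(ng, 2);  // col 0: n_i, col 1: s_i
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    int gi = g[vox(x, y, z, X, Y)];
    if (gi == 0) continue;
    double sum = 0.0; int cnt = 0;
    for (int dz = -1; dz <= 1; ++dz) for (int dy = -1; dy <= 1; ++dy) for (int dx = -1; dx <= 1; ++dx) {
      if (dx == 0 && dy == 0 && dz == 0) continue;
      int nx = x + dx, ny = y + dy, nz = z + dz;
      if (nx < 0 || ny < 0 || nz < 0 || nx >= X || ny >= Y || nz >= Z) continue;
      int gj = g[vox(nx, ny, nz, X, Y)];
      if (gj != 0) { sum += gj; ++cnt; }
    }
    if (cnt == 0) continue;
    out(gi - 1, 0) += 1.0;
    out(gi - 1, 1) += std::fabs((double)gi - sum / cnt);
  }
  return out;
}

// 1D convolution of a 3D volume along one axis (0 = x, 1 = y, 2 = z).
// kernel index k aligns sample in[i + k - center].  mode 0 = periodic wrap,
// mode 1 = replicate nearest edge sample.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis, int center, int mode) {
  int X = dims[0], Y = dims[1], Z = dims[2];
  int L = kernel.size();
  NumericVector out(vol.size());
  int len = (axis == 0) ? X : (axis == 1) ? Y : Z;
  for (int z = 0; z < Z; ++z) for (int y = 0; y < Y; ++y) for (int x = 0; x < X; ++x) {
    double acc = 0.0;
    int pos = (axis == 0) ? x : (axis == 1) ? y : z;
    for (int k = 0; k < L; ++k) {
      int p = pos + k - center;
      if (mode == 0) { p = ((p % len) + len) % len; }
      else { if (p < 0) p = 0; if (p >= len) p = len - 1; }
      int xi = x, yi = y, zi = z;
      if (axis == 0) xi = p; else if (axis == 1) yi = p; else zi = p;
      acc += kernel[k] * vol[vox(xi, yi, zi, X, Y)];
    }
    out[vox(x, y, z, X, Y)] = acc;
  }
  return out;
}
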