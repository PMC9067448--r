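#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (squared), Felzenszwalb & Huttenlocher
// separable lower-envelope-of-parabolas scheme, with per-axis voxel spacing.
// Input: seed mask (TRUE = distance zero). Output: squared distance in mm^2.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double w2) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;  // envelope holds only finite parabolas
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = 0.0;
    while (k >= 0) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) --k; else break;
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
    } else {
      ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    int p = v[k];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_squared(LogicalVector seed, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(seed.size());
  for (R_xlen_t i = 0; i < seed.size(); ++i) D[i] = seed[i] ? 0.0 : INF;
  // pass along x (fastest-varying)
  {
    std::vector<double> f(nx), d(nx);
    double w2 = spacing[0] * spacing[0];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        bool any = false;
        for (int x = 0; x < nx; ++x) { f[x] = D[base + x]; if (f[x] < INF) any = true; }
        if (!any) continue;
        dt1d(f, d, nx, w2);
        for (int x = 0; x < nx; ++x) D[base + x] = d[x];
      }
  }
  {
    std::vector<double> f(ny), d(ny);
    double w2 = spacing[1] * spacing[1];
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        bool any = false;
        for (int y = 0; y < ny; ++y) { f[y] = D[base + (R_xlen_t)y * nx]; if (f[y] < INF) any = true; }
        if (!any) continue;
        dt1d(f, d, ny, w2);
        for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y];
      }
  }
  {
    std::vector<double> f(nz), d(nz);
    double w2 = spacing[2] * spacing[2];
    R_xlen_t stride = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        bool any = false;
        for (int z = 0; z < nz; ++z) { f[z] = D[base + z * stride]; if (f[z] < INF) any = true; }
        if (!any) continue;
        dt1d(f, d, nz, w2);
        for (int z = 0; z < nz; ++z) D[base + z * stride] = d[z];
      }
  }
  return D;
}

// ---------------------------------------------------------------------------
// Connected component labeling (6- or 26-connectivity), BFS in lexicographic
// scan order so labels are deterministic.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int man = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && man != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!mask[idx] || lab[idx]) continue;
        ++next;
        lab[idx] = next;
        q.push(idx);
        while (!q.empty()) {
          R_xlen_t cur = q.front(); q.pop();
          int cx = (int)(cur % nx);
          int cy = (int)((cur / nx) % ny);
          int cz = (int)(cur / ((R_xlen_t)nx * ny));
          for (size_t k = 0; k < dx.size(); ++k) {
            int px = cx + dx[k], py = cy + dy[k], pz = cz + dz[k];
            if (px < 0 || py < 0 || pz < 0 || px >= nx || py >= ny || pz >= nz) continue;
            R_xlen_t nidx = (R_xlen_t)pz * nx * ny + (R_xlen_t)py * nx + px;
            if (mask[nidx] && !lab[nidx]) { lab[nidx] = next; q.push(nidx); }
          }
        }
      }
  return lab;
}

// ---------------------------------------------------------------------------
// 3-D curve thinning. A border voxel is deleted when it is a simple point
// (Malandain-Bertrand characterization: one 26-component of foreground in the
// 26-neighborhood and one 6-component of background in the 18-neighborhood
// that is 6-adjacent to the center) and not a curve endpoint. Six directional
// subiterations with sequential re-checking keep the result centered and the
// topology intact.
// ---------------------------------------------------------------------------

static inline int off_index(int cx, int cy, int cz) { // -1..1 each -> 0..26
  return (cx + 1) + 3 * (cy + 1) + 9 * (cz + 1);
}

// foreground 26-components in the 26-neighborhood (center excluded)
static int count_fg26(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    ++comps;
    // DFS
    int stack[27]; int sp = 0; stack[sp++] = i; seen[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int ez = -1; ez <= 1; ++ez)
        for (int ey = -1; ey <= 1; ++ey)
          for (int ex = -1; ex <= 1; ++ex) {
            int px = cx + ex, py = cy + ey, pz = cz + ez;
            if (px < -1 || px > 1 || py < -1 || py > 1 || pz < -1 || pz > 1) continue;
            int j = off_index(px, py, pz);
            if (j == 13 || j == c || !nb[j] || seen[j]) continue;
            seen[j] = true; stack[sp++] = j;
          }
    }
  }
  return comps;
}

// background 6-components within the 18-neighborhood that touch a 6-neighbor
static int count_bg6(const bool nb[27]) {
  bool inN18[27];
  for (int i = 0; i < 27; ++i) {
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    int man = std::abs(cx) + std::abs(cy) + std::abs(cz);
    inN18[i] = (i != 13) && man <= 2;
  }
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; ++i) {
    int cx = i % 3 - 1, cy = (i / 3) % 3 - 1, cz = i / 9 - 1;
    if (std::abs(cx) + std::abs(cy) + std::abs(cz) != 1) continue; // 6-neighbors as seeds
    if (nb[i] || seen[i]) continue;
    ++comps;
    int stack[27]; int sp = 0; stack[sp++] = i; seen[i] = true;
    while (sp) {
      int c = stack[--sp];
      int ox = c % 3 - 1, oy = (c / 3) % 3 - 1, oz = c / 9 - 1;
      const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int px = ox + d6[k][0], py = oy + d6[k][1], pz = oz + d6[k][2];
        if (px < -1 || px > 1 || py < -1 || py > 1 || pz < -1 || pz > 1) continue;
        int j = off_index(px, py, pz);
        if (!inN18[j] || nb[j] || seen[j]) continue;
        seen[j] = true; stack[sp++] = j;
      }
    }
  }
  return comps;
}

// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<char> M(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) M[i] = mask[i] ? 1 : 0;
  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return M[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
  };
  auto neighborhood = [&](int x, int y, int z, bool nb[27]) {
    for (int cz = -1; cz <= 1; ++cz)
      for (int cy = -1; cy <= 1; ++cy)
        for (int cx = -1; cx <= 1; ++cx)
          nb[off_index(cx, cy, cz)] = at(x + cx, y + cy, z + cz) != 0;
  };
  auto fg_count = [&](const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
  };
  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<R_xlen_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            R_xlen_t idx = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
            if (!M[idx]) continue;
            if (at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue; // not border in d
            cand.push_back(idx);
          }
      for (R_xlen_t idx : cand) {
        int x = (int)(idx % nx);
        int y = (int)((idx / nx) % ny);
        int z = (int)(idx / ((R_xlen_t)nx * ny));
        if (!M[idx]) continue;
        bool nb[27];
        neighborhood(x, y, z, nb);
        int nfg = fg_count(nb);
        if (nfg <= 1) continue;                    // endpoint or isolated: keep
        if (count_fg26(nb) != 1) continue;         // would split foreground
        if (count_bg6(nb) != 1) continue;          // would create/merge cavities
        M[idx] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) out[i] = M[i] != 0;
  return out;
}
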