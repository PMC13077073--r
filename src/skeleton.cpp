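#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// offsets of the 3x3x3 neighbourhood, position p = dz+1 + 3*(dy+1) + 9*(dx+1)
static inline int chebyshev(int a, int b, int c) {
  int m = std::abs(a);
  if (std::abs(b) > m) m = std::abs(b);
  if (std::abs(c) > m) m = std::abs(c);
  return m;
}

// Topological simple-point test for 3D binary images (26/6 connectivity):
// p is simple iff the foreground of N26(p)\{p} has exactly one 26-component
// and the background of N18(p) has exactly one 6-component that touches a
// face neighbour of p. nb[27] holds the local foreground configuration.
static bool is_simple(const bool nb[27]) {
  int off[27][3];
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int p = (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
        off[p][0] = dz; off[p][1] = dy; off[p][2] = dx;
      }
  const int centre = 13;

  // --- foreground 26-components among the 26 neighbours ---
  bool seen[27] = {false};
  int ncomp_fg = 0;
  for (int p = 0; p < 27; ++p) {
    if (p == centre || !nb[p] || seen[p]) continue;
    ++ncomp_fg;
    if (ncomp_fg > 1) return false;
    std::queue<int> q; q.push(p); seen[p] = true;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v = 0; v < 27; ++v) {
        if (v == centre || seen[v] || !nb[v]) continue;
        if (chebyshev(off[u][0] - off[v][0], off[u][1] - off[v][1],
                      off[u][2] - off[v][2]) <= 1) {
          seen[v] = true; q.push(v);
        }
      }
    }
  }
  if (ncomp_fg != 1) return false;

  // --- background 6-components within the 18-neighbourhood ---
  bool seen2[27] = {false};
  int ncomp_bg = 0;
  for (int p = 0; p < 27; ++p) {
    int man = std::abs(off[p][0]) + std::abs(off[p][1]) + std::abs(off[p][2]);
    if (p == centre || man > 2 || nb[p] || seen2[p]) continue;
    if (man != 1) continue;  // grow components only from face neighbours
    ++ncomp_bg;
    if (ncomp_bg > 1) return false;
    std::queue<int> q; q.push(p); seen2[p] = true;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (int v = 0; v < 27; ++v) {
        int manv = std::abs(off[v][0]) + std::abs(off[v][1]) + std::abs(off[v][2]);
        if (v == centre || manv > 2 || nb[v] || seen2[v]) continue;
        if (std::abs(off[u][0] - off[v][0]) + std::abs(off[u][1] - off[v][1]) +
            std::abs(off[u][2] - off[v][2]) == 1) {
          seen2[v] = true; q.push(v);
        }
      }
    }
  }
  return ncomp_bg == 1;
}

struct Cand { double prio; int idx; };

// Distance-ordered homotopic thinning of a 3D mask to a curve skeleton.
// Border voxels are deleted in increasing order of the (anisotropic) EDT,
// one at a time, only while topologically simple and not a curve endpoint
// (<= 1 remaining 26-neighbour). Out-of-bounds counts as background.
// [[Rcpp::export]]
LogicalVector skeletonize3d_cpp(LogicalVector mask, NumericVector edt) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t n = (size_t)nz * ny * nx;
  std::vector<char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> bool {
    if (z < 0 || y < 0 || x < 0 || z >= nz || y >= ny || x >= nx) return false;
    return m[(size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x)] != 0;
  };
  auto fill_nb = [&](int z, int y, int x, bool nb[27]) {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz)
          nb[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = at(z + dz, y + dy, x + dx);
  };
  auto n26 = [&](int z, int y, int x) -> int {
    int c = 0;
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dx && !dy && !dz) continue;
          if (at(z + dz, y + dy, x + dx)) ++c;
        }
    return c;
  };
  auto is_border = [&](int z, int y, int x) -> bool {
    return !at(z + 1, y, x) || !at(z - 1, y, x) || !at(z, y + 1, x) ||
           !at(z, y - 1, x) || !at(z, y, x + 1) || !at(z, y, x - 1);
  };

  bool changed = true;
  bool nb[27];
  while (changed) {
    changed = false;
    std::vector<Cand> cands;
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y)
        for (int z = 0; z < nz; ++z) {
          size_t i = (size_t)z + (size_t)nz * ((size_t)y + (size_t)ny * x);
          if (!m[i] || !is_border(z, y, x)) continue;
          if (n26(z, y, x) <= 1) continue;  // endpoint (or isolated): keep
          fill_nb(z, y, x, nb);
          if (is_simple(nb)) cands.push_back({edt[i], (int)i});
        }
    std::stable_sort(cands.begin(), cands.end(),
                     [](const Cand& a, const Cand& b) { return a.prio < b.prio; });
    for (const Cand& c : cands) {
      size_t i = (size_t)c.idx;
      int x = (int)(i / ((size_t)nz * ny));
      int y = (int)((i / nz) % ny);
      int z = (int)(i % nz);
      if (!m[i] || n26(z, y, x) <= 1) continue;
      fill_nb(z, y, x, nb);
      if (!is_simple(nb)) continue;
      m[i] = 0;
      changed = true;
    }
  }

  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// 26-connectivity component labelling of a 3D logical array.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector mask) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(n);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t i = stack.back(); stack.pop_back();
      int x = (int)(i / ((size_t)nz * ny));
      int y = (int)((i / nz) % ny);
      int z = (int)(i % nz);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if ((!dx && !dy && !dz) || zz < 0 || yy < 0 || xx < 0 ||
                zz >= nz || yy >= ny || xx >= nx)
              continue;
            size_t j = (size_t)zz + (size_t)nz * ((size_t)yy + (size_t)ny * xx);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
    }
  }
  return lab;
}
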