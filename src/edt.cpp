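#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared distance transform (Felzenszwalb & Huttenlocher) with
// physical sample spacing s: parabolas sit at x_i = i * s.
static void dt1d(const std::vector<double>& f, double s, std::vector<double>& d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double xq = q * s;
    double sint;
    while (true) {
      double xv = v[k] * s;
      sint = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * s;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform of a 3D mask: for every voxel,
// the physical (micron) distance to the nearest background voxel centre.
// mask is a logical array dim (nz, ny, nx); spacing is c(z, y, x) in microns.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("mask must be a 3D array");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double sz = spacing[0], sy = spacing[1], sx = spacing[2];
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g((size_t)nz * ny * nx);
  // column-major: index = z + nz*(y + ny*x)
  for (size_t i = 0; i < g.size(); ++i) g[i] = mask[i] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along z (fastest-varying)
  f.resize(nz); d.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      size_t base = (size_t)nz * (y + (size_t)ny * x);
      bool any_fin = false;
      for (int z = 0; z < nz; ++z) { f[z] = g[base + z]; if (f[z] < INF) any_fin = true; }
      if (!any_fin) continue;
      dt1d(f, sz, d);
      for (int z = 0; z < nz; ++z) g[base + z] = d[z];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      bool any_fin = false;
      for (int y = 0; y < ny; ++y) {
        f[y] = g[z + (size_t)nz * (y + (size_t)ny * x)];
        if (f[y] < INF) any_fin = true;
      }
      if (!any_fin) continue;
      dt1d(f, sy, d);
      for (int y = 0; y < ny; ++y) g[z + (size_t)nz * (y + (size_t)ny * x)] = d[y];
    }
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = g[z + (size_t)nz * (y + (size_t)ny * x)];
      dt1d(f, sx, d);
      for (int x = 0; x < nx; ++x) g[z + (size_t)nz * (y + (size_t)ny * x)] = d[x];
    }

  NumericVector out((size_t)nz * ny * nx);
  for (size_t i = 0; i < g.size(); ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dim;
  return out;
}
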