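#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Intersection abscissa of the parabolas rooted at grid sites p and q
// (positions p*h, q*h, heights f[p], f[q]).  f values may be +Inf.
static inline double intersect(const std::vector<double>& f,
                               int p, int q, double h) {
  if (f[q] == INF) return INF;   // parabola at q never undercuts
  if (f[p] == INF) return -INF;  // parabola at q undercuts everywhere
  return ((f[q] + q * q * h * h) - (f[p] + p * p * h * h)) /
         (2.0 * h * (q - p));
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher 2012)
// with sample spacing h; f holds squared distances, +Inf = background.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double h, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = +INF;
  for (int q = 1; q < n; q++) {
    double s = intersect(f, v[k], q, h);
    bool replaced = false;
    while (s <= z[k]) {
      if (k == 0) {  // entire stack is background: q takes over
        v[0] = q;
        replaced = true;
        break;
      }
      k--;
      s = intersect(f, v[k], q, h);
    }
    if (replaced) continue;
    if (s == INF) continue;  // f[q] infinite: never the lower envelope
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = +INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q * h) k++;
    if (f[v[k]] == INF) { d[q] = INF; continue; }
    double dq = (q - v[k]) * h;
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// foreground voxel of a binary 3D mask, honoring anisotropic spacing.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);

  for (int z = 0; z < nz; z++)          // pass along x
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = out[base + x];
      dt1d(f, d, spacing[0], nx);
      for (int x = 0; x < nx; x++) out[base + x] = d[x];
    }
  for (int z = 0; z < nz; z++)          // pass along y
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = out[base + (R_xlen_t)y * nx];
      dt1d(f, d, spacing[1], ny);
      for (int y = 0; y < ny; y++) out[base + (R_xlen_t)y * nx] = d[y];
    }
  for (int y = 0; y < ny; y++)          // pass along z
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = out[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, spacing[2], nz);
      for (int z = 0; z < nz; z++) out[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  return out;
}
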