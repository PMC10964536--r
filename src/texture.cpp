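#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

static const int OFFS[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// Symmetric grey-level co-occurrence counts over the 13 unique 3D
// offsets. `q` holds 1..G inside the ROI and 0 outside (length nx*ny*nz,
// x fastest). Returns a length G*G count vector, code (a-1)*G + b.
// [[Rcpp::export(name = ".glcm_counts")]]
NumericVector glcm_counts(IntegerVector q, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector counts(G * G);
  for (int o = 0; o < 13; o++) {
    int dx = OFFS[o][0], dy = OFFS[o][1], dz = OFFS[o][2];
    int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
    int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
    int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
    for (int z = z0; z < z1; z++)
      for (int y = y0; y < y1; y++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        R_xlen_t nb = (R_xlen_t)(z + dz) * nx * ny + (R_xlen_t)(y + dy) * nx + dx;
        for (int x = x0; x < x1; x++) {
          int a = q[base + x], b = q[nb + x];
          if (a > 0 && b > 0) {
            counts[(a - 1) * G + (b - 1)] += 1.0;
            counts[(b - 1) * G + (a - 1)] += 1.0;
          }
        }
      }
  }
  return counts;
}

// Grey-level run statistics merged over the 13 directions: runs of
// equal grey level along each lattice line. Returns (Nr, sum 1/l^2,
// sum l^2, sum over g of n_g^2, sum over l of n_l^2).
// [[Rcpp::export(name = ".glrlm_stats")]]
NumericVector glrlm_stats(IntegerVector q, IntegerVector dim, int G) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int nmax = std::max(nx, std::max(ny, nz)) + 1;
  std::vector<double> ng(G + 1), nl(3 * nmax + 1);
  double nr = 0, sre = 0, lre = 0;
  auto at = [&](int x, int y, int z) -> int {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0;
    return q[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
  };
  std::fill(ng.begin(), ng.end(), 0.0);
  std::fill(nl.begin(), nl.end(), 0.0);
  for (int o = 0; o < 13; o++) {
    int dx = OFFS[o][0], dy = OFFS[o][1], dz = OFFS[o][2];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          int g = at(x, y, z);
          if (g == 0) continue;
          // run starts here if the backward neighbour differs
          if (at(x - dx, y - dy, z - dz) == g) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (at(cx, cy, cz) == g) {
            len++; cx += dx; cy += dy; cz += dz;
          }
          nr += 1;
          sre += 1.0 / ((double)len * len);
          lre += (double)len * len;
          ng[g] += 1;
          if (len < (int)nl.size()) nl[len] += 1;
        }
  }
  double gln = 0, rln = 0;
  for (int g = 1; g <= G; g++) gln += ng[g] * ng[g];
  for (size_t l = 1; l < nl.size(); l++) rln += nl[l] * nl[l];
  return NumericVector::create(nr, sre, lre, gln, rln);
}

// Per-block symmetric co-occurrence counts: `lv` is a 27 x B matrix of
// grey levels (1..G), `p1`/`p2` are within-block voxel index pairs
// (1-based, already expanded over the 13 offsets). Returns G*G x B
// counts.
// [[Rcpp::export(name = ".block_glcm_counts")]]
NumericMatrix block_glcm_counts(IntegerMatrix lv, IntegerVector p1,
                                IntegerVector p2, int G) {
  int B = lv.ncol();
  int np = p1.size();
  NumericMatrix counts(G * G, B);
  for (int b = 0; b < B; b++) {
    for (int i = 0; i < np; i++) {
      int a = lv(p1[i] - 1, b), c = lv(p2[i] - 1, b);
      counts((a - 1) * G + (c - 1), b) += 1.0;
      counts((c - 1) * G + (a - 1), b) += 1.0;
    }
  }
  return counts;
}
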