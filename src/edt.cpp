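#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// large finite stand-in for "no seed yet": infinities break the lower
// envelope intersection arithmetic (INF - INF), so use a value far above
// any realistic squared distance instead
static const double BIG = 1e20;

// 1-D squared Euclidean distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher) with physical sample spacing `h`.
// f holds squared distances on input; result written back into f.
static void edt_1d(std::vector<double>& f, double h) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  std::vector<double> d(n);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      // intersection abscissa in physical units (parabola p sits at h*p)
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < h * q) ++k;
    const int p = v[k];
    d[q] = h2 * (q - p) * (q - p) + f[p];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact anisotropic 3-D Euclidean distance transform: for every voxel,
// the squared distance (in physical units) to the nearest seed voxel.
// seeds: logical array, dims: int vector (3), spacing: per-axis sample size.
// [[Rcpp::export(name = ".edt3d_squared")]]
NumericVector edt3d_squared(LogicalVector seeds, IntegerVector dims,
                            NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(nx * ny * nz);
  for (int i = 0; i < out.size(); ++i)
    out[i] = seeds[i] ? 0.0 : BIG;

  std::vector<double> line;

  // pass along x (fastest-varying index)
  line.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      const int base = y * nx + z * nx * ny;
      for (int x = 0; x < nx; ++x) line[x] = out[base + x];
      edt_1d(line, spacing[0]);
      for (int x = 0; x < nx; ++x) out[base + x] = line[x];
    }

  // pass along y
  line.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      const int base = x + z * nx * ny;
      for (int y = 0; y < ny; ++y) line[y] = out[base + y * nx];
      edt_1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) out[base + y * nx] = line[y];
    }

  // pass along z
  line.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      const int base = x + y * nx;
      for (int z = 0; z < nz; ++z) line[z] = out[base + z * nx * ny];
      edt_1d(line, spacing[2]);
      for (int z = 0; z < nz; ++z) out[base + z * nx * ny] = line[z];
    }

  return out;
}
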