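#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform (lower envelope of parabolas), grid step h.
// f holds squared distances on entry (INF where no feature yet); overwritten.
static void dt1d(std::vector<double> &f, double h,
                 std::vector<int> &v, std::vector<double> &z,
                 std::vector<double> &d) {
  const int n = (int)f.size();
  const double h2 = h * h;
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
               (2.0 * h2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      if (k < 0) break;
      s = ((f[q] + h2 * q * q) - (f[v[k]] + h2 * v[k] * v[k])) /
          (2.0 * h2 * (q - v[k]));
    }
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF;
    } else {
      ++k; v[k] = q; z[k] = s;
    }
    z[k + 1] = INF;
  }
  if (k < 0) {            // no feature on this line
    std::fill(d.begin(), d.begin() + n, INF);
  } else {
    int j = 0;
    for (int q = 0; q < n; ++q) {
      while (z[j + 1] < q) ++j;
      const double dx = (double)(q - v[j]) * h;
      d[q] = dx * dx + f[v[j]];
    }
  }
  std::copy(d.begin(), d.begin() + n, f.begin());
}

//' @name edt_cpp
//' @title Squared Euclidean distance transform of a 3D feature array
//' @description For every voxel, the squared physical distance (spacing-aware,
//'   voxel centres as points) to the nearest nonzero (feature) voxel. Voxels of
//'   the feature set get 0; if the array has no feature voxel, all Inf.
//' @keywords internal
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector features, IntegerVector dims,
                      NumericVector spacing) {
  if (dims.size() != 3 || spacing.size() != 3)
    stop("edt_cpp expects 3D dims and spacing");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (features.size() != n) stop("feature array does not match dims");

  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i)
    g[i] = (features[i] == TRUE) ? 0.0 : INF;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      const R_xlen_t off = (R_xlen_t)iz * nx * ny + (R_xlen_t)iy * nx;
      for (int ix = 0; ix < nx; ++ix) line[ix] = g[off + ix];
      line.resize(nx); dt1d(line, spacing[0], v, z, d); line.resize(nmax);
      for (int ix = 0; ix < nx; ++ix) g[off + ix] = line[ix];
    }
  // pass along y (stride nx)
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      const R_xlen_t off = (R_xlen_t)iz * nx * ny + ix;
      for (int iy = 0; iy < ny; ++iy) line[iy] = g[off + (R_xlen_t)iy * nx];
      line.resize(ny); dt1d(line, spacing[1], v, z, d); line.resize(nmax);
      for (int iy = 0; iy < ny; ++iy) g[off + (R_xlen_t)iy * nx] = line[iy];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      const R_xlen_t off = (R_xlen_t)iy * nx + ix;
      for (int iz = 0; iz < nz; ++iz) line[iz] = g[off + (R_xlen_t)iz * sz];
      line.resize(nz); dt1d(line, spacing[2], v, z, d); line.resize(nmax);
      for (int iz = 0; iz < nz; ++iz) g[off + (R_xlen_t)iz * sz] = line[iz];
    }

  NumericVector out(n);
  std::copy(g.begin(), g.end(), out.begin());
  return out;
}
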