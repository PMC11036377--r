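#include <Rcpp.h>
using namespace Rcpp;

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing `w`; f is overwritten through `out`.
static void dt1d(const double *f, double *out, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double fq = f[q] + w2 * q * q, fv = f[v[k]] + w2 * v[k] * v[k];
      s = (fq - fv) / (2.0 * w2 * (q - v[k]));
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double d = w * (q - v[k]);
    out[q] = d * d + f[v[k]];
  }
}

// Exact anisotropic Euclidean distance transform: distance (in mm) from every
// voxel to the nearest TRUE voxel of `mask`.  Voxels of an all-FALSE mask get
// Inf.
// [[Rcpp::export]]
NumericVector edt_cpp(LogicalVector mask, NumericVector voxel_size) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = (R_xlen_t) nx * ny * nz;
  NumericVector out(n);
  out.attr("dim") = d;
  double *g = out.begin();
  // large finite sentinel instead of Inf: the parabola-intersection
  // arithmetic of dt1d is undefined for Inf - Inf
  const double BIG = 1e20;
  for (R_xlen_t t = 0; t < n; ++t) g[t] = mask[t] ? 0.0 : BIG;

  std::vector<double> f(std::max(nx, std::max(ny, nz)));
  std::vector<double> o(f.size());

  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      double *col = g + (R_xlen_t) nx * (j + (R_xlen_t) ny * k);
      for (int i = 0; i < nx; ++i) f[i] = col[i];
      dt1d(f.data(), o.data(), nx, voxel_size[0]);
      for (int i = 0; i < nx; ++i) col[i] = o[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = g[i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)];
      dt1d(f.data(), o.data(), ny, voxel_size[1]);
      for (int j = 0; j < ny; ++j)
        g[i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)] = o[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = g[i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)];
      dt1d(f.data(), o.data(), nz, voxel_size[2]);
      for (int k = 0; k < nz; ++k) {
        double v2 = o[k];
        g[i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)] =
            (v2 >= 1e19) ? INFINITY : std::sqrt(v2);
      }
    }
  return out;
}
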