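#include <Rcpp.h>
using namespace Rcpp;

// Trilinear / nearest sampling of a 3D volume at arbitrary voxel coordinates.
// Coordinates are 1-based (R convention); out-of-field positions get `fill`.
// [[Rcpp::export]]
NumericVector sample_volume_cpp(NumericVector vol,
                                NumericVector xi, NumericVector yi,
                                NumericVector zi,
                                int method, double fill) {
  IntegerVector d = vol.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = xi.size();
  NumericVector out(n);
  const double *v = vol.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double x = xi[t] - 1.0, y = yi[t] - 1.0, z = zi[t] - 1.0;
    if (method == 0) { // nearest
      int i = (int) std::floor(x + 0.5), j = (int) std::floor(y + 0.5),
          k = (int) std::floor(z + 0.5);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz)
        out[t] = fill;
      else
        out[t] = v[i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)];
    } else { // trilinear, fill outside the closed hull of voxel centers
      if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
        out[t] = fill;
        continue;
      }
      int i0 = (int) std::floor(x), j0 = (int) std::floor(y),
          k0 = (int) std::floor(z);
      if (i0 == nx - 1) --i0;
      if (j0 == ny - 1) --j0;
      if (k0 == nz - 1) --k0;
      if (nx == 1) i0 = 0;
      if (ny == 1) j0 = 0;
      if (nz == 1) k0 = 0;
      double fx = x - i0, fy = y - j0, fz = z - k0;
      int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
          k1 = std::min(k0 + 1, nz - 1);
      double acc = 0.0;
      for (int c = 0; c < 8; ++c) {
        int ii = (c & 1) ? i1 : i0;
        int jj = (c & 2) ? j1 : j0;
        int kk = (c & 4) ? k1 : k0;
        double w = ((c & 1) ? fx : 1 - fx) * ((c & 2) ? fy : 1 - fy) *
                   ((c & 4) ? fz : 1 - fz);
        acc += w * v[ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk)];
      }
      out[t] = acc;
    }
  }
  return out;
}

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Densify a coarse free-form-deformation control grid to a full voxel grid
// using clamped uniform cubic B-splines (separable).  Clamping replicates the
// edge coefficients so the basis keeps partition of unity; the densified
// field is therefore a convex combination of control values and bounded by
// their extrema.
// [[Rcpp::export]]
NumericVector ffd_densify_cpp(NumericVector coef, int nx, int ny, int nz) {
  IntegerVector cd = coef.attr("dim");
  const int cx = cd[0], cy = cd[1], cz = cd[2];
  NumericVector out((R_xlen_t) nx * ny * nz);
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  const double *cf = coef.begin();
  double *o = out.begin();

  // precompute per-axis neighbor indices and basis weights
  std::vector<int> ix(nx * 4), iy(ny * 4), iz(nz * 4);
  std::vector<double> wx(nx * 4), wy(ny * 4), wz(nz * 4);
  auto fill_axis = [](int n, int nc, std::vector<int> &idx,
                      std::vector<double> &w) {
    double h = (nc > 1) ? (double) (n - 1) / (nc - 1) : 1.0;
    for (int p = 0; p < n; ++p) {
      double s = (nc > 1) ? p / h : 0.0; // position in control space, 0-based
      int i0 = (int) std::floor(s);
      double u = s - i0;
      double b0 = (1 - u) * (1 - u) * (1 - u) / 6.0;
      double b1 = (3 * u * u * u - 6 * u * u + 4) / 6.0;
      double b2 = (-3 * u * u * u + 3 * u * u + 3 * u + 1) / 6.0;
      double b3 = u * u * u / 6.0;
      double bw[4] = {b0, b1, b2, b3};
      for (int t = 0; t < 4; ++t) {
        idx[p * 4 + t] = clampi(i0 - 1 + t, 0, nc - 1);
        w[p * 4 + t] = bw[t];
      }
    }
  };
  fill_axis(nx, cx, ix, wx);
  fill_axis(ny, cy, iy, wy);
  fill_axis(nz, cz, iz, wz);

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int c = 0; c < 4; ++c) {
          double wc = wz[k * 4 + c];
          int kk = iz[k * 4 + c];
          for (int b = 0; b < 4; ++b) {
            double wb = wc * wy[j * 4 + b];
            int jj = iy[j * 4 + b];
            const double *row = cf + (R_xlen_t) cx * (jj + (R_xlen_t) cy * kk);
            for (int a = 0; a < 4; ++a)
              acc += wb * wx[i * 4 + a] * row[ix[i * 4 + a]];
          }
        }
        o[i + (R_xlen_t) nx * (j + (R_xlen_t) ny * k)] = acc;
      }
  return out;
}
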