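#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// 3D convolution primitives for the UNet, via im2col + BLAS.
// Tensors are R arrays with dim (nx, ny, nz, channels), column-major.
// Weights for a k^3 convolution are flattened to a (k^3 * cin) x cout matrix
// whose row index matches the R array layout dim (k, k, k, cin, cout).

// col is voxel-major: (nvox) x (k^3 * cin); column r = tap + k^3 * ci holds
// the input value of channel ci at tap offset (da, db, dc), zero outside.
static void im2col_fill(const double *x, int nx, int ny, int nz, int cin,
                        int k, arma::mat &col) {
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const int r = (k - 1) / 2; // "same" zero padding, k odd
  col.zeros();
  for (int ci = 0; ci < cin; ++ci) {
    const double *xc = x + nvox * ci;
    for (int dc = -r; dc <= r; ++dc)
      for (int db = -r; db <= r; ++db)
        for (int da = -r; da <= r; ++da) {
          R_xlen_t cidx =
              (da + r) + k * ((db + r) + (R_xlen_t) k * (dc + r)) +
              (R_xlen_t) k * k * k * ci;
          double *dst = col.colptr(cidx);
          for (int kk = 0; kk < nz; ++kk) {
            int sz = kk + dc;
            if (sz < 0 || sz >= nz) continue;
            for (int jj = 0; jj < ny; ++jj) {
              int sy = jj + db;
              if (sy < 0 || sy >= ny) continue;
              int lo = std::max(0, -da), hi = std::min(nx, nx - da);
              const double *src =
                  xc + (R_xlen_t) nx * (sy + (R_xlen_t) ny * sz) + da;
              double *d0 = dst + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk);
              std::memcpy(d0 + lo, src + lo,
                          (size_t) (hi - lo) * sizeof(double));
            }
          }
        }
  }
}

static arma::mat im2col(const double *x, int nx, int ny, int nz, int cin,
                        int k) {
  arma::mat col((R_xlen_t) nx * ny * nz, (R_xlen_t) k * k * k * cin);
  im2col_fill(x, nx, ny, nz, cin, k, col);
  return col;
}

static void col2im(const arma::mat &col, double *gx, int nx, int ny, int nz,
                   int cin, int k) {
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const int r = (k - 1) / 2;
  for (int ci = 0; ci < cin; ++ci) {
    double *xc = gx + nvox * ci;
    for (int dc = -r; dc <= r; ++dc)
      for (int db = -r; db <= r; ++db)
        for (int da = -r; da <= r; ++da) {
          R_xlen_t cidx =
              (da + r) + k * ((db + r) + (R_xlen_t) k * (dc + r)) +
              (R_xlen_t) k * k * k * ci;
          const double *src0 = col.colptr(cidx);
          for (int kk = 0; kk < nz; ++kk) {
            int sz = kk + dc;
            if (sz < 0 || sz >= nz) continue;
            for (int jj = 0; jj < ny; ++jj) {
              int sy = jj + db;
              if (sy < 0 || sy >= ny) continue;
              int lo = std::max(0, -da), hi = std::min(nx, nx - da);
              double *dst =
                  xc + (R_xlen_t) nx * (sy + (R_xlen_t) ny * sz) + da;
              const double *s0 =
                  src0 + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk);
              for (int ii = lo; ii < hi; ++ii) dst[ii] += s0[ii];
            }
          }
        }
  }
}

// [[Rcpp::export]]
SEXP conv3_forward_cpp(NumericVector x, NumericMatrix w,
                       NumericVector bias, int k, bool return_col = false) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int cout = w.ncol();
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  NumericMatrix colr(nvox, (R_xlen_t) k * k * k * cin);
  arma::mat col(colr.begin(), nvox, colr.ncol(), false);
  im2col_fill(x.begin(), nx, ny, nz, cin, k, col);
  arma::mat wm(w.begin(), w.nrow(), cout, false);
  NumericVector res(nvox * cout);
  res.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  arma::mat out(res.begin(), nvox, cout, false);
  out = col * wm; // nvox x cout, matches the array layout
  for (int c = 0; c < cout; ++c) out.col(c) += bias[c];
  if (return_col) return List::create(_["y"] = res, _["col"] = colr);
  return res;
}

// Returns list(gx, gw, gb) for upstream gradient `gout`.  A column
// matrix cached from the forward pass avoids recomputing im2col.
// [[Rcpp::export]]
List conv3_backward_cpp(NumericVector x, NumericMatrix w, NumericVector gout,
                        int k, Nullable<NumericMatrix> col_cache =
                            R_NilValue) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int cout = w.ncol();
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  arma::mat col;
  if (col_cache.isNotNull()) {
    NumericMatrix cc(col_cache);
    col = arma::mat(cc.begin(), nvox, cc.ncol(), false);
  } else {
    col = im2col(x.begin(), nx, ny, nz, cin, k);
  }
  arma::mat gm(gout.begin(), nvox, cout, false); // nvox x cout view
  arma::mat wm(w.begin(), w.nrow(), cout, false);

  NumericMatrix gw(w.nrow(), cout);
  arma::mat gwm(gw.begin(), w.nrow(), cout, false);
  gwm = col.t() * gm; // (k3*cin) x cout

  NumericVector gb(cout);
  for (int c = 0; c < cout; ++c) gb[c] = arma::accu(gm.col(c));

  arma::mat gcol = gm * wm.t(); // nvox x (k3*cin)
  NumericVector gx(nvox * cin);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  col2im(gcol, gx.begin(), nx, ny, nz, cin, k);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed convolution, kernel 2^3, stride 2 (non-overlapping taps).
// Weight layout: array dim (2, 2, 2, cin, cout) flattened to (8*cin) x cout.
// [[Rcpp::export]]
NumericVector upconv2_forward_cpp(NumericVector x, NumericMatrix w,
                                  NumericVector bias) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int cout = w.ncol();
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const R_xlen_t onvox = (R_xlen_t) ox * oy * oz;
  arma::mat xm(x.begin(), nvox, cin, false);
  NumericVector res(onvox * cout);
  res.attr("dim") = IntegerVector::create(ox, oy, oz, cout);
  double *o = res.begin();
  for (int c = 0; c < cout; ++c)
    for (R_xlen_t v = 0; v < onvox; ++v) o[c * onvox + v] = bias[c];
  for (int t = 0; t < 8; ++t) { // tap offset (a, b, c2) in {0,1}^3
    int a = t & 1, b = (t >> 1) & 1, c2 = (t >> 2) & 1;
    arma::mat wt(cin, cout);
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co)
        wt(ci, co) = w(a + 2 * b + 4 * c2 + 8 * ci, co);
    arma::mat out = xm * wt; // nvox x cout
    for (int co = 0; co < cout; ++co) {
      double *oc = o + (R_xlen_t) co * onvox;
      const double *ov = out.colptr(co);
      for (int kk = 0; kk < nz; ++kk)
        for (int jj = 0; jj < ny; ++jj)
          for (int ii = 0; ii < nx; ++ii)
            oc[(2 * ii + a) +
               (R_xlen_t) ox * ((2 * jj + b) + (R_xlen_t) oy * (2 * kk + c2))] +=
                ov[ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk)];
    }
  }
  return res;
}

// [[Rcpp::export]]
List upconv2_backward_cpp(NumericVector x, NumericMatrix w,
                          NumericVector gout) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cin = d[3];
  const int cout = w.ncol();
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const R_xlen_t onvox = (R_xlen_t) ox * oy * oz;
  arma::mat xm(x.begin(), nvox, cin, false);
  const double *g = gout.begin();

  NumericMatrix gw(w.nrow(), cout);
  NumericVector gb(cout);
  NumericVector gx(nvox * cin);
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  arma::mat gxm(gx.begin(), nvox, cin, false);

  for (int co = 0; co < cout; ++co) {
    double s = 0;
    const double *gc = g + (R_xlen_t) co * onvox;
    for (R_xlen_t v = 0; v < onvox; ++v) s += gc[v];
    gb[co] = s;
  }
  for (int t = 0; t < 8; ++t) {
    int a = t & 1, b = (t >> 1) & 1, c2 = (t >> 2) & 1;
    arma::mat gt(nvox, cout); // gathered gradient at this tap
    for (int co = 0; co < cout; ++co) {
      const double *gc = g + (R_xlen_t) co * onvox;
      double *dst = gt.colptr(co);
      for (int kk = 0; kk < nz; ++kk)
        for (int jj = 0; jj < ny; ++jj)
          for (int ii = 0; ii < nx; ++ii)
            dst[ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk)] =
                gc[(2 * ii + a) +
                   (R_xlen_t) ox *
                       ((2 * jj + b) + (R_xlen_t) oy * (2 * kk + c2))];
    }
    arma::mat gwt = xm.t() * gt; // cin x cout
    arma::mat wt(cin, cout);
    for (int ci = 0; ci < cin; ++ci)
      for (int co = 0; co < cout; ++co) {
        gw(a + 2 * b + 4 * c2 + 8 * ci, co) += gwt(ci, co);
        wt(ci, co) = w(a + 2 * b + 4 * c2 + 8 * ci, co);
      }
    gxm += gt * wt.t();
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Max pooling 2^3, stride 2.  Returns list(y, idx) where idx holds 0-based
// linear indices into the input used for the backward scatter.
// [[Rcpp::export]]
List maxpool2_forward_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cc = d[3];
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const R_xlen_t onvox = (R_xlen_t) ox * oy * oz;
  NumericVector y(onvox * cc);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cc);
  NumericVector idx(onvox * cc); // store as double to avoid int overflow
  const double *xv = x.begin();
  double *yv = y.begin(), *iv = idx.begin();
  for (int c = 0; c < cc; ++c) {
    const double *xc = xv + (R_xlen_t) c * nvox;
    for (int kk = 0; kk < oz; ++kk)
      for (int jj = 0; jj < oy; ++jj)
        for (int ii = 0; ii < ox; ++ii) {
          double best = -INFINITY;
          R_xlen_t bi = 0;
          for (int dc = 0; dc < 2; ++dc)
            for (int db = 0; db < 2; ++db)
              for (int da = 0; da < 2; ++da) {
                R_xlen_t p = (2 * ii + da) +
                             (R_xlen_t) nx * ((2 * jj + db) +
                                              (R_xlen_t) ny * (2 * kk + dc));
                if (xc[p] > best) {
                  best = xc[p];
                  bi = p;
                }
              }
          R_xlen_t q =
              ii + (R_xlen_t) ox * (jj + (R_xlen_t) oy * kk) + (R_xlen_t) c * onvox;
          yv[q] = best;
          iv[q] = (double) (bi + (R_xlen_t) c * nvox);
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward_cpp(NumericVector gout, NumericVector idx,
                                    IntegerVector in_dim) {
  R_xlen_t n = (R_xlen_t) in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  double *g = gx.begin();
  const double *go = gout.begin(), *iv = idx.begin();
  for (R_xlen_t t = 0; t < gout.size(); ++t) g[(R_xlen_t) iv[t]] += go[t];
  return gx;
}

// Trilinear x2 upsampling (half-voxel aligned) and its adjoint.
// [[Rcpp::export]]
NumericVector upsample2_forward_cpp(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2], cc = d[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const R_xlen_t onvox = (R_xlen_t) ox * oy * oz;
  NumericVector y(onvox * cc);
  y.attr("dim") = IntegerVector::create(ox, oy, oz, cc);
  const double *xv = x.begin();
  double *yv = y.begin();
  auto coord = [](int o, int n, int &i0, int &i1, double &f) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    i0 = (int) std::floor(s);
    i1 = std::min(i0 + 1, n - 1);
    f = s - i0;
  };
  for (int c = 0; c < cc; ++c) {
    const double *xc = xv + (R_xlen_t) c * nvox;
    double *yc = yv + (R_xlen_t) c * onvox;
    for (int kk = 0; kk < oz; ++kk) {
      int k0, k1; double fz; coord(kk, nz, k0, k1, fz);
      for (int jj = 0; jj < oy; ++jj) {
        int j0, j1; double fy; coord(jj, ny, j0, j1, fy);
        for (int ii = 0; ii < ox; ++ii) {
          int i0, i1; double fx; coord(ii, nx, i0, i1, fx);
          double v =
              (1 - fz) * ((1 - fy) * ((1 - fx) * xc[i0 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k0)] +
                                      fx * xc[i1 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k0)]) +
                          fy * ((1 - fx) * xc[i0 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k0)] +
                                fx * xc[i1 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k0)])) +
              fz * ((1 - fy) * ((1 - fx) * xc[i0 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k1)] +
                                fx * xc[i1 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k1)]) +
                    fy * ((1 - fx) * xc[i0 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k1)] +
                          fx * xc[i1 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k1)]));
          yc[ii + (R_xlen_t) ox * (jj + (R_xlen_t) oy * kk)] = v;
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_backward_cpp(NumericVector gout, IntegerVector in_dim) {
  const int nx = in_dim[0], ny = in_dim[1], nz = in_dim[2], cc = in_dim[3];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  const R_xlen_t nvox = (R_xlen_t) nx * ny * nz;
  const R_xlen_t onvox = (R_xlen_t) ox * oy * oz;
  NumericVector gx(nvox * cc);
  gx.attr("dim") = in_dim;
  const double *gv = gout.begin();
  double *xv = gx.begin();
  auto coord = [](int o, int n, int &i0, int &i1, double &f) {
    double s = (o + 0.5) / 2.0 - 0.5;
    if (s < 0) s = 0;
    if (s > n - 1) s = n - 1;
    i0 = (int) std::floor(s);
    i1 = std::min(i0 + 1, n - 1);
    f = s - i0;
  };
  for (int c = 0; c < cc; ++c) {
    double *xc = xv + (R_xlen_t) c * nvox;
    const double *gc = gv + (R_xlen_t) c * onvox;
    for (int kk = 0; kk < oz; ++kk) {
      int k0, k1; double fz; coord(kk, nz, k0, k1, fz);
      for (int jj = 0; jj < oy; ++jj) {
        int j0, j1; double fy; coord(jj, ny, j0, j1, fy);
        for (int ii = 0; ii < ox; ++ii) {
          int i0, i1; double fx; coord(ii, nx, i0, i1, fx);
          double g = gc[ii + (R_xlen_t) ox * (jj + (R_xlen_t) oy * kk)];
          xc[i0 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k0)] += (1 - fz) * (1 - fy) * (1 - fx) * g;
          xc[i1 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k0)] += (1 - fz) * (1 - fy) * fx * g;
          xc[i0 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k0)] += (1 - fz) * fy * (1 - fx) * g;
          xc[i1 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k0)] += (1 - fz) * fy * fx * g;
          xc[i0 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k1)] += fz * (1 - fy) * (1 - fx) * g;
          xc[i1 + (R_xlen_t) nx * (j0 + (R_xlen_t) ny * k1)] += fz * (1 - fy) * fx * g;
          xc[i0 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k1)] += fz * fy * (1 - fx) * g;
          xc[i1 + (R_xlen_t) nx * (j1 + (R_xlen_t) ny * k1)] += fz * fy * fx * g;
        }
      }
    }
  }
  return gx;
}
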