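#include <Rcpp.h>
using namespace Rcpp;

// Linear-interpolation parallel-beam backprojection.
// filt_t: [n_det x n_ang] ramp-filtered projections (detector index fastest,
// so interpolation reads are contiguous); cth/sth: cos/sin of the projection
// angles; out_n: side of the square output grid; weight: angular quadrature
// weight applied to the sum.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filt_t, NumericVector cth,
                              NumericVector sth, int out_n, double weight) {
  const int n_det = filt_t.nrow();
  const int n_ang = filt_t.ncol();
  const double centre_det = (n_det + 1) / 2.0;
  const double centre_out = (out_n + 1) / 2.0;
  NumericMatrix recon(out_n, out_n);

  for (int a = 0; a < n_ang; ++a) {
    const double c = cth[a], s = sth[a];
    const double *col = &filt_t(0, a);
    for (int j = 0; j < out_n; ++j) {        // column (x coordinate)
      const double x = (j + 1) - centre_out;
      const double xc = x * c + centre_det;
      for (int i = 0; i < out_n; ++i) {      // row (y coordinate)
        const double y = (i + 1) - centre_out;
        const double t = xc + y * s;
        const int i0 = (int)std::floor(t);
        if (i0 >= 1 && i0 < n_det) {
          const double frac = t - i0;
          recon(i, j) += col[i0 - 1] * (1.0 - frac) + col[i0] * frac;
        }
      }
    }
  }
  for (int j = 0; j < out_n; ++j)
    for (int i = 0; i < out_n; ++i) recon(i, j) *= weight;
  return recon;
}
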