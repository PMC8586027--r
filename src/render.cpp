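#include <Rcpp.h>
using namespace Rcpp;

// Accumulate unit-mass isotropic Gaussians (per-molecule sigma) on a
// regular grid. Pixel (i, j) is centred at ((j - 0.5) * p + x0,
// (i - 0.5) * p + y0); each Gaussian is truncated at trunc_sigma.
// [[Rcpp::export]]
NumericMatrix cpp_render_gaussians(NumericVector x, NumericVector y,
                                   NumericVector sigma,
                                   double x0, double y0, double p,
                                   int nr, int nc, double trunc_sigma) {
  NumericMatrix img(nr, nc);
  const double inv_sqrt2pi = 0.3989422804014327;
  int n = x.size();
  std::vector<double> gx, gy;
  for (int m = 0; m < n; ++m) {
    double s = sigma[m];
    double r = trunc_sigma * s;
    int jlo = std::max(1, (int)std::floor((x[m] - r - x0) / p) + 1);
    int jhi = std::min(nc, (int)std::ceil((x[m] + r - x0) / p));
    int ilo = std::max(1, (int)std::floor((y[m] - r - y0) / p) + 1);
    int ihi = std::min(nr, (int)std::ceil((y[m] + r - y0) / p));
    if (jlo > jhi || ilo > ihi) continue;
    gx.assign(jhi - jlo + 1, 0.0);
    gy.assign(ihi - ilo + 1, 0.0);
    double a = inv_sqrt2pi / s * p;
    for (int j = jlo; j <= jhi; ++j) {
      double d = ((j - 0.5) * p + x0 - x[m]) / s;
      gx[j - jlo] = a * std::exp(-0.5 * d * d);
    }
    for (int i = ilo; i <= ihi; ++i) {
      double d = ((i - 0.5) * p + y0 - y[m]) / s;
      gy[i - ilo] = a * std::exp(-0.5 * d * d);
    }
    for (int j = jlo; j <= jhi; ++j)
      for (int i = ilo; i <= ihi; ++i)
        img(i - 1, j - 1) += gy[i - ilo] * gx[j - jlo];
  }
  return img;
}
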