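#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state `zi`
// (a[0] must be 1).  Matches the recurrence used by standard
// signal-processing toolboxes, so zero-phase filtering can be built on
// top with odd extension + steady-state initial conditions.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(const NumericVector& b,
                             const NumericVector& a,
                             const NumericVector& x,
                             const NumericVector& zi) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nf = std::max(nb, na) - 1;  // filter order (state size)
  if ((int)zi.size() != nf) stop("zi must have length max(length(a), length(b)) - 1");
  std::vector<double> bb(nf + 1, 0.0), aa(nf + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(zi.begin(), zi.end());
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double xi = x[i];
    const double yi = bb[0] * xi + (nf > 0 ? z[0] : 0.0);
    for (int j = 0; j < nf - 1; ++j) {
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    }
    if (nf > 0) z[nf - 1] = bb[nf] * xi - aa[nf] * yi;
    y[i] = yi;
  }
  return y;
}
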