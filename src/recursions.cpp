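#include <Rcpp.h>
using namespace Rcpp;

// First-order recursive tracking:
//   y[1] = init;  y[i+1] = x[i+1]/beta + (1 - 1/beta) * y[i]
// [[Rcpp::export]]
NumericVector track_rec_cpp(NumericVector x, double beta, double init) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  if (n == 0) return y;
  const double b = 1.0 / beta, r = 1.0 - 1.0 / beta;
  y[0] = init;
  for (R_xlen_t i = 1; i < n; ++i) y[i] = b * x[i] + r * y[i - 1];
  return y;
}

// Leaky differencing:
//   y[1] = init;  y[i+1] = (y[i] + x[i+1] - x[i]) / beta
// [[Rcpp::export]]
NumericVector leaky_rec_cpp(NumericVector x, double beta, double init) {
  R_xlen_t n = x.size();
  NumericVector y(n);
  if (n == 0) return y;
  const double b = 1.0 / beta;
  y[0] = init;
  for (R_xlen_t i = 1; i < n; ++i) y[i] = b * (y[i - 1] + x[i] - x[i - 1]);
  return y;
}
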