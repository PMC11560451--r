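// Elementwise rectifier and its gate, dimension attributes preserved.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector relu_cpp(NumericVector x) {
  NumericVector y = clone(x);
  const R_xlen_t n = y.size();
  double* p = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector drelu_cpp(NumericVector d, NumericVector y) {
  NumericVector out = clone(d);
  const R_xlen_t n = out.size();
  double* p = REAL(out);
  const double* q = REAL(y);
  for (R_xlen_t i = 0; i < n; ++i)
    if (q[i] <= 0) p[i] = 0;
  return out;
}
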