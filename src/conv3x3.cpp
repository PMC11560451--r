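// Zero-padded 3x3 convolution over (channels, h*w, batch) activation cubes.
// Each of the nine taps becomes one full-width GEMM against a shifted copy of
// the input, so the bulk of the work runs inside BLAS. The position index is
// column-major with the image row fastest, so a (cin, h*w*batch) matrix
// reinterpreted as (cin*h, w*batch) supports row shifts as row-block ranges
// and column shifts as per-slice column ranges (shifts never cross slices).
//
// Weight layout: W is (cout, cin*9); column block t*cin + ch corresponds to
// tap t in {0..8} with row offset t % 3 - 1 and column offset t / 3 - 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Xv: (cin*h, w*bt) view of the activations. Returns S(r, c) = Xv(r+dr, c+dc)
// within each w-column slice, zero elsewhere.
static mat shifted(const mat& Xv, int cin, int h, int w, int bt,
                   int dr, int dc) {
  mat S(Xv.n_rows, Xv.n_cols, fill::zeros);
  const int r0 = std::max(0, -dr), r1 = h - 1 - std::max(0, dr);
  const int c0 = std::max(0, -dc), c1 = w - 1 - std::max(0, dc);
  if (r1 < r0 || c1 < c0) return S;
  for (int s = 0; s < bt; ++s) {
    const int off = s * w;
    S.submat(r0 * cin, off + c0, (r1 + 1) * cin - 1, off + c1) =
      Xv.submat((r0 + dr) * cin, off + c0 + dc,
                (r1 + dr + 1) * cin - 1, off + c1 + dc);
  }
  return S;
}

// [[Rcpp::export]]
arma::cube conv3x3_fwd_cpp(const arma::cube& X, const arma::mat& W,
                           const arma::vec& b, int h, int w) {
  const int cin = X.n_rows;
  const int bt = X.n_slices;
  const int cout = W.n_rows;
  const int L = h * w;
  const mat Xall(const_cast<double*>(X.memptr()), cin, L * bt, false, true);
  const mat Xv(const_cast<double*>(X.memptr()), cin * h, w * bt, false, true);
  mat Y(cout, L * bt);
  Y.each_col() = b;
  for (int t = 0; t < 9; ++t) {
    const int dr = t % 3 - 1, dc = t / 3 - 1;
    mat Xsh = shifted(Xv, cin, h, w, bt, dr, dc);
    const mat Xsm(Xsh.memptr(), cin, L * bt, false, true);
    Y += W.cols(t * cin, t * cin + cin - 1) * Xsm;
  }
  return cube(Y.memptr(), cout, L, bt);
}

// [[Rcpp::export]]
Rcpp::List conv3x3_bwd_cpp(const arma::cube& dY, const arma::cube& X,
                           const arma::mat& W, int h, int w) {
  const int cin = X.n_rows;
  const int bt = X.n_slices;
  const int cout = W.n_rows;
  const int L = h * w;
  const mat dYall(const_cast<double*>(dY.memptr()), cout, L * bt, false, true);
  const mat Xv(const_cast<double*>(X.memptr()), cin * h, w * bt, false, true);
  cube dX(cin, L, bt, fill::zeros);
  mat dXv(dX.memptr(), cin * h, w * bt, false, true);
  mat dW(cout, cin * 9, fill::zeros);
  vec db = sum(dYall, 1);
  for (int t = 0; t < 9; ++t) {
    const int dr = t % 3 - 1, dc = t / 3 - 1;
    mat Xsh = shifted(Xv, cin, h, w, bt, dr, dc);
    const mat Xsm(Xsh.memptr(), cin, L * bt, false, true);
    dW.cols(t * cin, t * cin + cin - 1) = dYall * Xsm.t();
    // dX(r+dr, c+dc) += W_t^T dY(r, c): reverse-shift accumulate
    mat Tb = W.cols(t * cin, t * cin + cin - 1).t() * dYall;  // cin x L*bt
    const mat Tbv(Tb.memptr(), cin * h, w * bt, false, true);
    const int r0 = std::max(0, -dr), r1 = h - 1 - std::max(0, dr);
    const int c0 = std::max(0, -dc), c1 = w - 1 - std::max(0, dc);
    if (r1 < r0 || c1 < c0) continue;
    for (int s = 0; s < bt; ++s) {
      const int off = s * w;
      dXv.submat((r0 + dr) * cin, off + c0 + dc,
                 (r1 + dr + 1) * cin - 1, off + c1 + dc) +=
        Tbv.submat(r0 * cin, off + c0, (r1 + 1) * cin - 1, off + c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dx") = dX,
                            Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}
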