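// SIMPLS partial least squares kernel.
//
// The selection algorithms (CARS Monte Carlo runs, random-frog subset search)
// evaluate tens of thousands of small PLS fits per call, so the fit and the
// fold-wise RMSECV loop live here. Model-level fitting in R wraps these.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// SIMPLS (de Jong 1993) regression coefficients on mean-centered data.
// Returns p x A matrix; column a holds coefficients using components 1..a,
// for predictions yhat = mean(y) + (X - colmeans(X)) * B.col(a-1).
static mat simpls_coef(const mat& X, const vec& y, unsigned int ncomp) {
  const unsigned int n = X.n_rows, p = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat X0 = X.each_row() - xm;
  vec y0 = y - ym;

  unsigned int A = std::min<unsigned int>(ncomp, std::min<unsigned int>(p, n - 1));
  mat R(p, A, fill::zeros);   // X weights
  vec Q(A, fill::zeros);      // y loadings
  mat V(p, A, fill::zeros);   // orthonormal basis for X loadings
  mat B(p, ncomp, fill::zeros);

  vec s = X0.t() * y0;        // p x 1 cross-covariance
  unsigned int a_done = 0;
  for (unsigned int a = 0; a < A; ++a) {
    vec r = s;
    vec t = X0 * r;
    t -= mean(t);
    double nt = std::sqrt(dot(t, t));
    if (nt < 1e-12 || !std::isfinite(nt)) break;
    t /= nt; r /= nt;
    vec pl = X0.t() * t;      // X loading
    double q = dot(y0, t);
    vec v = pl;
    if (a > 0) {
      vec proj = V.head_cols(a).t() * pl;
      v -= V.head_cols(a) * proj;
    }
    double nv = std::sqrt(dot(v, v));
    if (nv < 1e-12) break;
    v /= nv;
    V.col(a) = v;
    s -= v * dot(v, s);
    R.col(a) = r;
    Q(a) = q;
    B.col(a) = R.head_cols(a + 1) * Q.head(a + 1);
    a_done = a + 1;
  }
  // deflation exhausted: later component counts inherit the last valid fit
  for (unsigned int a = a_done; a < ncomp; ++a)
    B.col(a) = (a_done > 0) ? B.col(a_done - 1) : vec(p, fill::zeros);
  return B;
}

// [[Rcpp::export]]
Rcpp::List pls_fit_cpp(const arma::mat& X, const arma::vec& y, int ncomp) {
  mat B = simpls_coef(X, y, (unsigned int)ncomp);
  return Rcpp::List::create(
    Rcpp::Named("coef") = B,
    Rcpp::Named("x_means") = rowvec(mean(X, 0)),
    Rcpp::Named("y_mean") = mean(y));
}

// Fold-wise RMSECV for component counts 1..max_lv.
// fold_id: 1-based fold label per row. Per fold the component count is capped
// at min(max_lv, p, n_train - 1); per-lv squared errors above a fold's cap
// reuse that fold's largest fitted model so every lv gets a full-sample RMSECV.
// [[Rcpp::export]]
arma::vec rmsecv_cpp(const arma::mat& X, const arma::vec& y,
                     const arma::ivec& fold_id, int max_lv) {
  const unsigned int n = X.n_rows, p = X.n_cols;
  int K = fold_id.max();
  vec sse(max_lv, fill::zeros);
  for (int k = 1; k <= K; ++k) {
    uvec te = find(fold_id == k);
    uvec tr = find(fold_id != k);
    if (te.n_elem == 0 || tr.n_elem < 2) continue;
    mat Xtr = X.rows(tr), Xte = X.rows(te);
    vec ytr = y.elem(tr), yte = y.elem(te);
    unsigned int cap = std::min<unsigned int>((unsigned int)max_lv,
                        std::min<unsigned int>(p, tr.n_elem - 1));
    mat B = simpls_coef(Xtr, ytr, cap);
    rowvec xm = mean(Xtr, 0);
    double ym = mean(ytr);
    mat Xte0 = Xte.each_row() - xm;
    for (int a = 0; a < max_lv; ++a) {
      unsigned int col = std::min<unsigned int>((unsigned int)a, cap - 1);
      vec pred = ym + Xte0 * B.col(col);
      vec e = yte - pred;
      sse(a) += dot(e, e);
    }
  }
  return sqrt(sse / (double)n);
}
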