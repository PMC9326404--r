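// .Call registration for the compiled SIMPLS kernel
#include <RcppArmadillo.h>
#include <Rcpp.h>
#include <R_ext/Rdynload.h>

using namespace Rcpp;

Rcpp::List pls_fit_cpp(const arma::mat& X, const arma::vec& y, int ncomp);
RcppExport SEXP _leafspec_pls_fit_cpp(SEXP XSEXP, SEXP ySEXP, SEXP ncompSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< const arma::mat& >::type X(XSEXP);
    Rcpp::traits::input_parameter< const arma::vec& >::type y(ySEXP);
    Rcpp::traits::input_parameter< int >::type ncomp(ncompSEXP);
    rcpp_result_gen = Rcpp::wrap(pls_fit_cpp(X, y, ncomp));
    return rcpp_result_gen;
END_RCPP
}

arma::vec rmsecv_cpp(const arma::mat& X, const arma::vec& y, const arma::ivec& fold_id, int max_lv);
RcppExport SEXP _leafspec_rmsecv_cpp(SEXP XSEXP, SEXP ySEXP, SEXP fold_idSEXP, SEXP max_lvSEXP) {
BEGIN_RCPP
    Rcpp::RObject rcpp_result_gen;
    Rcpp::traits::input_parameter< const arma::mat& >::type X(XSEXP);
    Rcpp::traits::input_parameter< const arma::vec& >::type y(ySEXP);
    Rcpp::traits::input_parameter< const arma::ivec& >::type fold_id(fold_idSEXP);
    Rcpp::traits::input_parameter< int >::type max_lv(max_lvSEXP);
    rcpp_result_gen = Rcpp::wrap(rmsecv_cpp(X, y, fold_id, max_lv));
    return rcpp_result_gen;
END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
    {"_leafspec_pls_fit_cpp", (DL_FUNC) &_leafspec_pls_fit_cpp, 3},
    {"_leafspec_rmsecv_cpp", (DL_FUNC) &_leafspec_rmsecv_cpp, 4},
    {NULL, NULL, 0}
};

RcppExport void R_init_leafspec(DllInfo *dll) {
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
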