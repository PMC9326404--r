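# .Call wrappers for the compiled SIMPLS kernel (src/pls.cpp)

pls_fit_cpp <- function(X, y, ncomp) {
  .Call(`_leafspec_pls_fit_cpp`, X, y, ncomp)
}

rmsecv_cpp <- function(X, y, fold_id, max_lv) {
  .Call(`_leafspec_rmsecv_cpp`, X, y, fold_id, max_lv)
}
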