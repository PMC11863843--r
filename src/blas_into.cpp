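#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
using namespace Rcpp;

// C := t(A) %*% B written into a caller-owned buffer. Avoids allocating
// (and page-faulting) the large weight-gradient matrices on every
// optimizer step.
// [[Rcpp::export]]
void crossprod_into(NumericMatrix A, NumericMatrix B, NumericMatrix C) {
  int k = A.nrow(), m = A.ncol(), n = B.ncol();
  if (B.nrow() != k || C.nrow() != m || C.ncol() != n)
    stop("crossprod_into: dimension mismatch");
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("T", "N", &m, &n, &k, &one, REAL(A), &k, REAL(B), &k,
                  &zero, REAL(C), &m FCONE FCONE);
}
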