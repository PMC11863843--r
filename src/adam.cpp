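#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update. theta, m and v are owned by the training loop
// (freshly copied at its start), so writing through them is safe and
// avoids reallocating the multi-megabyte weight matrices every step.
// bc1 = 1 - beta1^t and bc2 = 1 - beta2^t are the bias corrections.
// Raw restrict pointers let the compiler vectorize the sqrt/div chain,
// which dominates on large weight matrices.
// [[Rcpp::export]]
void adam_step_inplace(NumericVector theta, NumericVector m,
                       NumericVector v, NumericVector grad,
                       double lr, double beta1, double beta2,
                       double eps, double bc1, double bc2) {
  R_xlen_t n = theta.size();
  if (m.size() != n || v.size() != n || grad.size() != n)
    stop("adam_step_inplace: length mismatch");
  double* __restrict__ t = REAL(theta);
  double* __restrict__ mm = REAL(m);
  double* __restrict__ vv = REAL(v);
  const double* __restrict__ g = REAL(grad);
  const double lr1 = lr / bc1;
  const double isq2 = 1.0 / std::sqrt(bc2);
  const double om1 = 1.0 - beta1, om2 = 1.0 - beta2;
  for (R_xlen_t i = 0; i < n; ++i) {
    double gi = g[i];
    double mi = beta1 * mm[i] + om1 * gi;
    double vi = beta2 * vv[i] + om2 * gi * gi;
    mm[i] = mi;
    vv[i] = vi;
    t[i] -= lr1 * mi / (std::sqrt(vi) * isq2 + eps);
  }
}
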