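#include <Rcpp.h>
using namespace Rcpp;

// Log-space evaluation of POPAN-style history probabilities.
//
// A history's probability is a double sum over the latent entry occasion b
// and last-alive occasion d:
//   sum_b sum_d  beta_b * prod_{j=b}^{d-1} phi_j * death(d)
//                * prod_{j=b}^{d} p_j^{x_j} (1-p_j)^{1-x_j}
// with death(d) = 1 - phi_d for d < T and 1 for d = T (the individual may
// outlive the study).  Translocated individuals have known entry b = 1 and
// no beta factor (the model conditions on the release).
//
// All inputs arrive as logs; -Inf encodes a structural zero (e.g. beta = 0
// before tau, or 1 - p = 0 at the release).  Sums of logs never subtract,
// so -Inf propagates cleanly and never produces NaN.

static double logsumexp_acc(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double t : v) if (t > m) m = t;
  if (!R_FINITE(m)) return m;  // all -Inf (or empty)
  double s = 0.0;
  for (double t : v) if (R_FINITE(t)) s += std::exp(t - m);
  return m + std::log(s);
}

static double term_bd(int b, int d, int T, bool transloc,
                      const int* x,
                      const double* lbeta, const double* lphi,
                      const double* l1mphi, const double* lp,
                      const double* l1mp) {
  double t = transloc ? 0.0 : lbeta[b - 1];
  for (int j = b; j <= d - 1; ++j) t += lphi[j - 1];
  if (d < T) t += l1mphi[d - 1];
  if (x) {
    for (int j = b; j <= d; ++j) t += x[j - 1] ? lp[j - 1] : l1mp[j - 1];
  } else {
    for (int j = b; j <= d; ++j) t += l1mp[j - 1];
  }
  return t;
}

// [[Rcpp::export]]
NumericVector cpp_log_prob_histories(IntegerMatrix X, IntegerVector f,
                                     IntegerVector dl, LogicalVector transloc,
                                     int tau, NumericVector lbeta,
                                     NumericVector lphi, NumericVector l1mphi,
                                     NumericVector lp, NumericVector l1mp) {
  const int U = X.nrow(), T = X.ncol();
  NumericVector out(U);
  std::vector<double> terms;
  std::vector<int> xi(T);
  for (int i = 0; i < U; ++i) {
    for (int j = 0; j < T; ++j) xi[j] = X(i, j);
    const bool tr = transloc[i];
    const int bmin = tr ? 1 : tau;
    const int bmax = tr ? 1 : f[i];
    terms.clear();
    for (int b = bmin; b <= bmax; ++b)
      for (int d = dl[i]; d <= T; ++d)
        terms.push_back(term_bd(b, d, T, tr, xi.data(),
                                REAL(lbeta), REAL(lphi), REAL(l1mphi),
                                REAL(lp), REAL(l1mp)));
    out[i] = logsumexp_acc(terms);
  }
  return out;
}

// Probability that a (wild) superpopulation member is never detected:
// entry anywhere from tau, any death occasion, all detections missed.
// [[Rcpp::export]]
double cpp_log_prob_never(int T, int tau, NumericVector lbeta,
                          NumericVector lphi, NumericVector l1mphi,
                          NumericVector l1mp) {
  std::vector<double> terms;
  for (int b = tau; b <= T; ++b)
    for (int d = b; d <= T; ++d)
      terms.push_back(term_bd(b, d, T, false, nullptr,
                              REAL(lbeta), REAL(lphi), REAL(l1mphi),
                              nullptr, REAL(l1mp)));
  return logsumexp_acc(terms);
}
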