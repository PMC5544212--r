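#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adaptive PSI trial loop for one series: expected-entropy SOA selection,
// Bernoulli response from the observer's true probabilities, Bayes update.
// C1 = p(r=1 | theta, soa), C0 = 1 - C1, M1 = C1*log(C1), M0 = C0*log(C0),
// all n_theta x n_soa. tie_order is 1-based, smallest |SOA| first and
// negative before positive; an SOA later in that order must improve the
// expected entropy by more than 1e-12 to displace the incumbent.
// [[Rcpp::export]]
List run_psi_series_cpp(NumericMatrix C1, NumericMatrix M1,
                        NumericMatrix C0, NumericMatrix M0,
                        NumericVector prior, NumericVector p_true,
                        NumericVector u, IntegerVector tie_order) {
  const int n_theta = C1.nrow();
  const int n_soa = C1.ncol();
  const int n_trials = u.size();
  const double tol = 1e-12;

  std::vector<double> post(prior.begin(), prior.end());
  std::vector<double> plp(n_theta);
  std::vector<double> eh(n_soa);
  IntegerVector soa_idx(n_trials);
  IntegerVector resp(n_trials);

  for (int t = 0; t < n_trials; ++t) {
    for (int k = 0; k < n_theta; ++k)
      plp[k] = post[k] > 0.0 ? post[k] * std::log(post[k]) : 0.0;
    for (int s = 0; s < n_soa; ++s) {
      const double *c1 = &C1(0, s), *c0 = &C0(0, s);
      const double *m1 = &M1(0, s), *m0 = &M0(0, s);
      double w1 = 0.0, w0 = 0.0, s1 = 0.0, s0 = 0.0;
      for (int k = 0; k < n_theta; ++k) {
        const double p = post[k];
        w1 += c1[k] * p;
        w0 += c0[k] * p;
        s1 += m1[k] * p + c1[k] * plp[k];
        s0 += m0[k] * p + c0[k] * plp[k];
      }
      const double h1 = w1 > 0.0 ? w1 * std::log(w1) : 0.0;
      const double h0 = w0 > 0.0 ? w0 * std::log(w0) : 0.0;
      eh[s] = h1 - s1 + h0 - s0;
    }
    int best = tie_order[0] - 1;
    for (int j = 1; j < n_soa; ++j) {
      const int s = tie_order[j] - 1;
      if (eh[s] < eh[best] - tol) best = s;
    }
    const int r = (u[t] < p_true[best]) ? 1 : 0;
    const double *lik = r ? &C1(0, best) : &C0(0, best);
    double z = 0.0;
    for (int k = 0; k < n_theta; ++k) {
      post[k] *= lik[k];
      z += post[k];
    }
    if (z <= 0.0) stop("posterior update failed: zero total likelihood");
    for (int k = 0; k < n_theta; ++k) post[k] /= z;
    soa_idx[t] = best + 1;
    resp[t] = r;
  }
  return List::create(_["soa_idx"] = soa_idx,
                      _["response"] = resp,
                      _["posterior"] = NumericVector(post.begin(), post.end()));
}
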