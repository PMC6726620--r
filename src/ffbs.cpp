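#include <Rcpp.h>
using namespace Rcpp;

// Forward-filter backward-sampling for a 2-state Gaussian HMM with shared
// emission SD. States: 0 (lower mean) and 1. Transition matrix rows
// (p00, 1-p00) and (1-p11, p11); the chain is initialized from its
// stationary distribution. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
IntegerVector ffbs_gauss2(NumericVector y, double mu0, double mu1,
                          double sigma, double p00, double p11) {
  int n = y.size();
  NumericMatrix alpha(n, 2);
  double s2 = sigma * sigma;
  double pi1 = (1.0 - p00) / (2.0 - p00 - p11);
  double pi0 = 1.0 - pi1;

  // forward filtering with per-step normalization; emissions enter via
  // a max-subtracted exponential to avoid underflow at small sigma
  double l0 = -0.5 * (y[0] - mu0) * (y[0] - mu0) / s2;
  double l1 = -0.5 * (y[0] - mu1) * (y[0] - mu1) / s2;
  double m = l0 > l1 ? l0 : l1;
  double a0 = pi0 * std::exp(l0 - m);
  double a1 = pi1 * std::exp(l1 - m);
  double z = a0 + a1;
  alpha(0, 0) = a0 / z;
  alpha(0, 1) = a1 / z;

  for (int t = 1; t < n; ++t) {
    double pr0 = alpha(t - 1, 0) * p00 + alpha(t - 1, 1) * (1.0 - p11);
    double pr1 = alpha(t - 1, 0) * (1.0 - p00) + alpha(t - 1, 1) * p11;
    l0 = -0.5 * (y[t] - mu0) * (y[t] - mu0) / s2;
    l1 = -0.5 * (y[t] - mu1) * (y[t] - mu1) / s2;
    m = l0 > l1 ? l0 : l1;
    a0 = pr0 * std::exp(l0 - m);
    a1 = pr1 * std::exp(l1 - m);
    z = a0 + a1;
    if (z <= 0.0) { a0 = pr0; a1 = pr1; z = a0 + a1; }
    alpha(t, 0) = a0 / z;
    alpha(t, 1) = a1 / z;
  }

  // backward sampling
  IntegerVector s(n);
  s[n - 1] = (unif_rand() < alpha(n - 1, 1)) ? 1 : 0;
  for (int t = n - 2; t >= 0; --t) {
    double w0, w1;
    if (s[t + 1] == 0) {
      w0 = alpha(t, 0) * p00;
      w1 = alpha(t, 1) * (1.0 - p11);
    } else {
      w0 = alpha(t, 0) * (1.0 - p00);
      w1 = alpha(t, 1) * p11;
    }
    double tot = w0 + w1;
    s[t] = (tot <= 0.0) ? s[t + 1] : ((unif_rand() < w1 / tot) ? 1 : 0);
  }
  return s;
}

// Viterbi MAP state path for the same 2-state Gaussian HMM.
// [[Rcpp::export]]
IntegerVector viterbi_gauss2(NumericVector y, double mu0, double mu1,
                             double sigma, double p00, double p11) {
  int n = y.size();
  double s2 = sigma * sigma;
  double pi1 = (1.0 - p00) / (2.0 - p00 - p11);
  double pi0 = 1.0 - pi1;
  std::vector<double> d0(n), d1(n);
  std::vector<int> b0(n), b1(n);
  double la = std::log(p00), lb = std::log(1.0 - p00);
  double lc = std::log(1.0 - p11), ld = std::log(p11);

  d0[0] = std::log(pi0) - 0.5 * (y[0] - mu0) * (y[0] - mu0) / s2;
  d1[0] = std::log(pi1) - 0.5 * (y[0] - mu1) * (y[0] - mu1) / s2;
  for (int t = 1; t < n; ++t) {
    double e0 = -0.5 * (y[t] - mu0) * (y[t] - mu0) / s2;
    double e1 = -0.5 * (y[t] - mu1) * (y[t] - mu1) / s2;
    double v00 = d0[t - 1] + la, v10 = d1[t - 1] + lc;
    if (v00 >= v10) { d0[t] = v00 + e0; b0[t] = 0; }
    else            { d0[t] = v10 + e0; b0[t] = 1; }
    double v01 = d0[t - 1] + lb, v11 = d1[t - 1] + ld;
    if (v11 >= v01) { d1[t] = v11 + e1; b1[t] = 1; }
    else            { d1[t] = v01 + e1; b1[t] = 0; }
  }
  IntegerVector s(n);
  s[n - 1] = d1[n - 1] > d0[n - 1] ? 1 : 0;
  for (int t = n - 2; t >= 0; --t)
    s[t] = (s[t + 1] == 0) ? b0[t + 1] : b1[t + 1];
  return s;
}
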