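// EM core for the ordered binomial mixture used in tumor-purity
// estimation.  Operates on unique (x, N) pairs with multiplicities; the
// R wrapper handles aggregation, initialization and the PurityFit object.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".emBinomCore")]]
List emBinomCore(NumericVector x, NumericVector n, NumericVector wts,
                 NumericVector lch, NumericVector thetaInit, double tol,
                 int maxIter) {
  const int m = x.size();
  const int K = thetaInit.size();
  std::vector<double> theta(thetaInit.begin(), thetaInit.end());
  std::vector<double> piw(K, 1.0 / K);
  double sumw = 0.0;
  for (int i = 0; i < m; ++i) sumw += wts[i];

  double ll = R_NegInf;
  bool converged = false, decreased = false;
  int iter = 0;
  std::vector<double> lp(K), wk(K), sg(K), sgx(K), sgn(K);

  while (iter < maxIter) {
    ++iter;
    double llNew = 0.0;
    std::fill(sg.begin(), sg.end(), 0.0);
    std::fill(sgx.begin(), sgx.end(), 0.0);
    std::fill(sgn.begin(), sgn.end(), 0.0);
    std::vector<double> lth(K), l1th(K);
    for (int k = 0; k < K; ++k) {
      lth[k] = std::log(theta[k]);
      l1th[k] = std::log1p(-theta[k]);
    }
    // E-step: responsibilities and loglik at the current parameters
    for (int i = 0; i < m; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        lp[k] = lch[i] + x[i] * lth[k] + (n[i] - x[i]) * l1th[k];
        if (lp[k] > mx) mx = lp[k];
      }
      double rs = 0.0;
      for (int k = 0; k < K; ++k) {
        wk[k] = piw[k] * std::exp(lp[k] - mx);
        rs += wk[k];
      }
      llNew += wts[i] * (mx + std::log(rs));
      const double gi = wts[i] / rs;
      for (int k = 0; k < K; ++k) {
        const double g = gi * wk[k];
        sg[k] += g;
        sgx[k] += g * x[i];
        sgn[k] += g * n[i];
      }
    }
    if (llNew < ll - 1e-7) {  // EM must not decrease the loglik
      decreased = true;
      ll = llNew;
      break;
    }
    const bool done = R_FINITE(ll) && std::fabs(llNew - ll) < tol;
    ll = llNew;
    if (done) {
      converged = true;
      break;
    }
    // M-step, then ordered-model projection (sort descending, clamp 0.5)
    double psum = 0.0;
    for (int k = 0; k < K; ++k) {
      piw[k] = std::max(sg[k] / sumw, 1e-12);
      psum += piw[k];
      theta[k] = std::min(std::max(sgx[k] / sgn[k], 1e-9), 0.5);
    }
    for (int k = 0; k < K; ++k) piw[k] /= psum;
    std::vector<int> ord(K);
    for (int k = 0; k < K; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return theta[a] > theta[b]; });
    std::vector<double> th2(K), pi2(K);
    for (int k = 0; k < K; ++k) {
      th2[k] = theta[ord[k]];
      pi2[k] = piw[ord[k]];
    }
    theta = th2;
    piw = pi2;
  }
  return List::create(
      _["theta"] = NumericVector(theta.begin(), theta.end()),
      _["pi"] = NumericVector(piw.begin(), piw.end()), _["loglik"] = ll,
      _["iter"] = iter, _["converged"] = converged,
      _["decreased"] = decreased);
}
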