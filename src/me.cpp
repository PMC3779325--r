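// Reconstructed-process log-likelihood for constant-rate birth-death with
// instantaneous mass-extinction events, conditioned on crown age and
// survival of both crown lineages. Piecewise-analytic survival recursions;
// reduces exactly to the plain birth-death likelihood when all rho = 1.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double me_loglik_cpp(NumericVector bt, double lambda, double mu,
                     NumericVector evAge, NumericVector evRho) {
  const int m = bt.size();        // n - 1 branching times, descending
  const int n = m + 1;
  double r = lambda - mu;
  if (std::fabs(r) < 1e-10) r = 1e-10;
  const int ne = evAge.size();    // ascending event ages

  // piece starts (ascending): 0, evAge...
  std::vector<double> brk(ne + 1), Ebrk(ne + 1), logDbrk(ne + 1);
  brk[0] = 0.0; Ebrk[0] = 0.0; logDbrk[0] = 0.0;
  for (int j = 0; j < ne; ++j) {
    double E0 = Ebrk[j];
    double A = lambda * (1.0 - E0), B = mu - lambda * E0;
    double d = evAge[j] - brk[j];
    double eg = std::exp(-r * d);
    double denom = A - B * eg;
    if (denom <= 0.0) return R_NegInf;
    Ebrk[j + 1] = (1.0 - evRho[j]) + evRho[j] * (mu * (1.0 - E0) - B * eg) / denom;
    double num = A * std::exp(r * d) - B;
    if (num <= 0.0 || A - B <= 0.0) return R_NegInf;
    logDbrk[j + 1] = logDbrk[j] + std::log(evRho[j]) + r * d -
      2.0 * (std::log(num) - std::log(A - B));
    brk[j + 1] = evAge[j];
  }

  double lnL = R::lgammafn(n) + (n - 2) * std::log(lambda);
  double crownE = 0.0, crownLogD = 0.0;
  for (int i = 0; i < m; ++i) {
    double age = bt[i];
    int j = ne;
    while (j > 0 && brk[j] > age) --j;
    double E0 = Ebrk[j];
    double A = lambda * (1.0 - E0), B = mu - lambda * E0;
    double d = age - brk[j];
    double eg = std::exp(-r * d);
    double denom = A - B * eg;
    if (denom <= 0.0 || A - B <= 0.0) return R_NegInf;
    double E = (mu * (1.0 - E0) - B * eg) / denom;
    double num = A * std::exp(r * d) - B;
    if (num <= 0.0) return R_NegInf;
    double logD = logDbrk[j] + r * d - 2.0 * (std::log(num) - std::log(A - B));
    if (E >= 1.0) return R_NegInf;
    lnL += logD;
    if (i == 0) { crownE = E; crownLogD = logD; }
  }
  lnL += crownLogD - 2.0 * std::log(1.0 - crownE);
  return lnL;
}
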