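// BiSSE pruning likelihood.
//
// Coupled extinction/data ODEs integrated rootward along each branch with an
// adaptive Cash-Karp Runge-Kutta scheme, D renormalised against underflow.
// Convention: speciation factor applied at every internal node merge except
// the root; root state handled by FitzJohn weighting or equal weights.

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct BisseRates {
  double lam0, lam1, mu0, mu1, q01, q10;
};

inline void deriv(const BisseRates& r, const double* y, double* dy) {
  const double E0 = y[0], E1 = y[1], D0 = y[2], D1 = y[3];
  dy[0] = r.mu0 - (r.lam0 + r.mu0 + r.q01) * E0 + r.q01 * E1 + r.lam0 * E0 * E0;
  dy[1] = r.mu1 - (r.lam1 + r.mu1 + r.q10) * E1 + r.q10 * E0 + r.lam1 * E1 * E1;
  dy[2] = -(r.lam0 + r.mu0 + r.q01) * D0 + r.q01 * D1 + 2.0 * r.lam0 * E0 * D0;
  dy[3] = -(r.lam1 + r.mu1 + r.q10) * D1 + r.q10 * D0 + 2.0 * r.lam1 * E1 * D1;
}

// Cash-Karp embedded 4(5) coefficients
const double b21 = 1.0 / 5.0;
const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0, b63 = 575.0 / 13824.0,
             b64 = 44275.0 / 110592.0, b65 = 253.0 / 4096.0;
const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
const double d1 = 2825.0 / 27648.0, d3 = 18575.0 / 48384.0, d4 = 13525.0 / 55296.0,
             d5 = 277.0 / 14336.0, d6 = 1.0 / 4.0;

// integrate y over [0, len]; returns log-rescaling applied to D components
double integrate_branch(const BisseRates& r, double* y, double len,
                        double rtol, double atol) {
  if (len <= 0.0) return 0.0;
  double t = 0.0;
  double rate_scale = r.lam0 + r.lam1 + r.mu0 + r.mu1 + r.q01 + r.q10 + 1e-8;
  double h = std::min(len, 0.1 / rate_scale);
  double logscale = 0.0;
  double k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], ytmp[4], y5[4], yerr[4];
  int iter = 0;
  while (t < len) {
    if (++iter > 1000000) stop("BiSSE integrator failed to converge on a branch");
    if (t + h > len) h = len - t;
    deriv(r, y, k1);
    for (int i = 0; i < 4; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    deriv(r, ytmp, k2);
    for (int i = 0; i < 4; ++i) ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    deriv(r, ytmp, k3);
    for (int i = 0; i < 4; ++i) ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    deriv(r, ytmp, k4);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    deriv(r, ytmp, k5);
    for (int i = 0; i < 4; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] + b64 * k4[i] + b65 * k5[i]);
    deriv(r, ytmp, k6);
    double errmax = 0.0;
    for (int i = 0; i < 4; ++i) {
      y5[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      double y4 = y[i] + h * (d1 * k1[i] + d3 * k3[i] + d4 * k4[i] + d5 * k5[i] + d6 * k6[i]);
      yerr[i] = y5[i] - y4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      errmax = std::max(errmax, std::fabs(yerr[i]) / sc);
    }
    if (errmax <= 1.0) {
      t += h;
      for (int i = 0; i < 4; ++i) y[i] = y5[i];
      // guard E within [0,1]
      for (int i = 0; i < 2; ++i) {
        if (y[i] < 0.0) y[i] = 0.0;
        if (y[i] > 1.0) y[i] = 1.0;
      }
      double m = std::fabs(y[2]) + std::fabs(y[3]);
      if (m > 0.0 && m < 1e-20) {
        y[2] /= m; y[3] /= m;
        logscale += std::log(m);
      }
      h *= std::min(5.0, 0.9 * std::pow(std::max(errmax, 1e-10), -0.2));
    } else {
      h *= std::max(0.2, 0.9 * std::pow(errmax, -0.25));
      if (h < 1e-14 * len) stop("BiSSE integrator step size underflow");
    }
  }
  return logscale;
}

}  // namespace

// [[Rcpp::export]]
double bisse_loglik_cpp(IntegerMatrix edge, NumericVector edgeLen, int nTip,
                        NumericMatrix tipD, NumericVector tipE,
                        NumericVector pars, int rootType, bool condSurv,
                        double rtol) {
  BisseRates r;
  r.lam0 = pars[0]; r.lam1 = pars[1];
  r.mu0 = pars[2]; r.mu1 = pars[3];
  r.q01 = pars[4]; r.q10 = pars[5];
  const double atol = rtol * 1e-2;
  const int nEdge = edge.nrow();
  const int nNode = nTip + nEdge / 2 + 1;  // binary rooted: nTip - 1 internals

  std::vector<double> prodD0(nNode, 1.0), prodD1(nNode, 1.0), Eacc(nNode, 0.0),
      E1acc(nNode, 0.0);
  std::vector<int> nchild(nNode, 0);
  double logscale = 0.0;
  int root = -1;

  for (int e = 0; e < nEdge; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    root = p;  // postorder: last parent seen is the root
    double y[4];
    if (c < nTip) {
      y[0] = tipE[0]; y[1] = tipE[1];
      y[2] = tipD(c, 0); y[3] = tipD(c, 1);
    } else {
      if (nchild[c] != 2)
        stop("tree must be strictly bifurcating (resolve polytomies first)");
      y[0] = Eacc[c] / 2.0; y[1] = E1acc[c] / 2.0;
      y[2] = r.lam0 * prodD0[c];
      y[3] = r.lam1 * prodD1[c];
      double m = std::fabs(y[2]) + std::fabs(y[3]);
      if (m <= 0.0) return R_NegInf;
      y[2] /= m; y[3] /= m;
      logscale += std::log(m);
    }
    logscale += integrate_branch(r, y, edgeLen[e], rtol, atol);
    prodD0[p] *= y[2];
    prodD1[p] *= y[3];
    Eacc[p] += y[0];
    E1acc[p] += y[1];
    nchild[p] += 1;
  }

  if (root < 0) stop("empty edge matrix");
  if (nchild[root] != 2)
    stop("tree must have a bifurcating root");
  double D0 = prodD0[root], D1 = prodD1[root];
  double E0 = Eacc[root] / nchild[root], E1 = E1acc[root] / nchild[root];
  double tot = D0 + D1;
  if (!(tot > 0.0) || !std::isfinite(tot)) return R_NegInf;

  double w0, w1;
  if (rootType == 0) { w0 = D0 / tot; w1 = D1 / tot; }
  else { w0 = 0.5; w1 = 0.5; }
  double L = w0 * D0 + w1 * D1;
  if (condSurv) {
    double s = w0 * r.lam0 * (1.0 - E0) * (1.0 - E0) +
               w1 * r.lam1 * (1.0 - E1) * (1.0 - E1);
    L /= s;
  }
  if (!(L > 0.0)) return R_NegInf;
  return std::log(L) + logscale;
}
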