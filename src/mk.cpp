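// Felsenstein pruning likelihood for a k-state Mk chain.
//
// Transition probabilities come from one eigendecomposition of Q per call
// (cheap inside optimisation loops); an ill-conditioned eigenbasis falls
// back to scaling-and-squaring matrix exponentials per branch.

#include <RcppArmadillo.h>
using namespace Rcpp;

static double mk_loglik_arma(const IntegerMatrix& edge,
                             const NumericVector& edgeLen, int nTip,
                             const NumericMatrix& tipL, const arma::mat& Q,
                             const NumericVector& rootPrior);

// [[Rcpp::export]]
double mk_loglik_cpp(IntegerMatrix edge, NumericVector edgeLen, int nTip,
                     NumericMatrix tipL, arma::mat Q, NumericVector rootPrior) {
  return mk_loglik_arma(edge, edgeLen, nTip, tipL, Q, rootPrior);
}

// negative log-likelihood of Pagel's independent (4 rates) or dependent
// (8 rates) joint model of two binary traits; Q assembled here so the
// optimiser loop stays free of R-level overhead
// [[Rcpp::export]]
double pagel_nll_cpp(NumericVector logRates, bool dependent,
                     IntegerMatrix edge, NumericVector edgeLen, int nTip,
                     NumericMatrix tipL) {
  arma::mat Q(4, 4, arma::fill::zeros);
  NumericVector r = clone(logRates);
  for (int i = 0; i < r.size(); ++i)
    r[i] = std::exp(std::min(r[i], 8.0));
  // state order: (x,y) = (0,0), (0,1), (1,0), (1,1)
  if (!dependent) {
    Q(0, 2) = r[0]; Q(1, 3) = r[0];   // x 0->1
    Q(2, 0) = r[1]; Q(3, 1) = r[1];   // x 1->0
    Q(0, 1) = r[2]; Q(2, 3) = r[2];   // y 0->1
    Q(1, 0) = r[3]; Q(3, 2) = r[3];   // y 1->0
  } else {
    Q(0, 2) = r[0]; Q(1, 3) = r[1];
    Q(2, 0) = r[2]; Q(3, 1) = r[3];
    Q(0, 1) = r[4]; Q(2, 3) = r[5];
    Q(1, 0) = r[6]; Q(3, 2) = r[7];
  }
  for (int i = 0; i < 4; ++i) Q(i, i) = -arma::accu(Q.row(i));
  NumericVector prior(4, 0.25);
  double ll = mk_loglik_arma(edge, edgeLen, nTip, tipL, Q, prior);
  if (!std::isfinite(ll)) return 1e10;
  return -ll;
}

static double mk_loglik_arma(const IntegerMatrix& edge,
                             const NumericVector& edgeLen, int nTip,
                             const NumericMatrix& tipL, const arma::mat& Q,
                             const NumericVector& rootPrior) {
  const int k = Q.n_rows;
  const int nEdge = edge.nrow();
  int maxNode = 0;
  for (int e = 0; e < nEdge; ++e) maxNode = std::max(maxNode, edge(e, 0));
  arma::mat prod(maxNode, k, arma::fill::ones);
  std::vector<int> nchild(maxNode, 0);
  double logscale = 0.0;
  int root = -1;

  bool use_eig = true;
  arma::cx_vec eval;
  arma::cx_mat evec, evinv;
  if (!arma::eig_gen(eval, evec, Q)) use_eig = false;
  if (use_eig && !arma::inv(evinv, evec)) use_eig = false;

  arma::vec Dc(k), msg(k);
  arma::cx_vec v(k), u(k);
  for (int e = 0; e < nEdge; ++e) {
    int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    root = p;
    if (c < nTip) {
      for (int i = 0; i < k; ++i) Dc[i] = tipL(c, i);
    } else {
      Dc = prod.row(c).t();
      double m = arma::accu(arma::abs(Dc));
      if (m <= 0.0) return R_NegInf;
      Dc /= m;
      logscale += std::log(m);
    }
    if (use_eig) {
      // msg = Re( V diag(exp(eval t)) V^-1 ) Dc, applied vector-wise
      v = evinv * arma::cx_vec(Dc, arma::vec(k, arma::fill::zeros));
      for (int i = 0; i < k; ++i) v[i] *= std::exp(eval[i] * edgeLen[e]);
      u = evec * v;
      for (int i = 0; i < k; ++i) msg[i] = std::max(u[i].real(), 0.0);
    } else {
      arma::mat P = arma::expmat(Q * edgeLen[e]);
      P.elem(arma::find(P < 0.0)).zeros();
      msg = P * Dc;
    }
    for (int i = 0; i < k; ++i) prod(p, i) *= msg[i];
    nchild[p] += 1;
  }

  if (root < 0) stop("empty edge matrix");
  double L = 0.0;
  for (int i = 0; i < k; ++i) L += rootPrior[i] * prod(root, i);
  if (!(L > 0.0) || !std::isfinite(L)) return R_NegInf;
  return std::log(L) + logscale;
}
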