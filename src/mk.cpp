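// Felsenstein pruning for the extended Mk model.
//
// Edges must be supplied in postorder (every child row before its parent's
// row). Partial likelihoods are rescaled per node to avoid underflow; the
// accumulated log factors are carried up the tree.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List mk_pruning_cpp(const arma::umat& edge, const arma::vec& edge_len,
                    int ntip, const arma::mat& tipL, const arma::mat& Q,
                    arma::vec pi, bool fitzjohn, bool want_extras) {
  const int k = Q.n_cols;
  const int nedge = edge.n_rows;
  const int nnode = nedge + 1;
  arma::mat L(nnode, k, arma::fill::ones);
  L.rows(0, ntip - 1) = tipL;
  arma::vec logsc(nnode, arma::fill::zeros);
  arma::cube P(k, k, nedge);
  for (int e = 0; e < nedge; ++e) {
    if (edge_len[e] == 0.0) P.slice(e).eye();
    else P.slice(e) = arma::expmat(Q * edge_len[e]);
  }
  for (int e = 0; e < nedge; ++e) {
    const int p = edge(e, 0) - 1, c = edge(e, 1) - 1;
    arma::vec msg = P.slice(e) * L.row(c).t();
    L.row(p) %= msg.t();
    logsc[p] += logsc[c];
    double m = L.row(p).max();
    if (!(m > 0.0)) {
      return List::create(_["loglik"] = R_NegInf);
    }
    L.row(p) /= m;
    logsc[p] += std::log(m);
  }
  const int root = ntip;  // 0-based index of node ntip+1
  arma::rowvec Lr = L.row(root);
  if (fitzjohn) pi = (Lr / arma::accu(Lr)).t();
  double lik = arma::dot(Lr.t(), pi);
  double loglik = (lik > 0.0) ? std::log(lik) + logsc[root] : R_NegInf;
  if (!want_extras) return List::create(_["loglik"] = loglik);
  return List::create(_["loglik"] = loglik,
                      _["partials"] = L,
                      _["pi"] = pi,
                      _["P"] = P);
}
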