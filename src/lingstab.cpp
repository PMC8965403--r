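// Compiled kernels: matrix exponential, pruning likelihood for the 4-state
// hidden-rates model, and batched sister-difference sums for the D statistic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// exp(Q * t) for a square rate matrix Q
// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& Q, double t) {
  if (t < 0) stop("negative branch length");
  arma::mat P = arma::expmat(Q * t);
  return P;
}

// Felsenstein pruning over a binary tree.
// edge: (2N-2) x 2 integer matrix in postorder (children before parents),
// 1-based node ids, tips 1..ntip. len: edge lengths. tip_partials: k x ntip.
// Root treated with the conditional-likelihood (FitzJohn/Maddison) weighting:
// prior_i = L_i / sum_j L_j, likelihood = sum_i prior_i * L_i.
// Returns log-likelihood plus the scaled root partial and its log scale.
// [[Rcpp::export]]
List cpp_pruning(const arma::imat& edge, const arma::vec& len,
                 const arma::mat& tip_partials, const arma::mat& Q,
                 int n_node) {
  const int ntip = tip_partials.n_cols;
  const int k = tip_partials.n_rows;
  const int ntot = ntip + n_node;
  arma::mat part(k, ntot, arma::fill::ones);
  part.cols(0, ntip - 1) = tip_partials;
  arma::vec logscale(ntot, arma::fill::zeros);
  arma::ivec nseen(ntot, arma::fill::zeros);
  if (!len.is_finite()) stop("non-finite branch length");
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    arma::mat P = arma::expmat(Q * len(e));
    part.col(par) %= P * part.col(ch);
    logscale(par) += logscale(ch);
    if (++nseen(par) == 2) {
      double m = part.col(par).max();
      if (m <= 0) return List::create(_["loglik"] = R_NegInf,
                                      _["root_partial"] = part.col(par),
                                      _["log_scale"] = logscale(par));
      part.col(par) /= m;
      logscale(par) += std::log(m);
    }
  }
  int root = edge(edge.n_rows - 1, 0) - 1;
  arma::vec L = part.col(root);
  double s = arma::accu(L);
  if (s <= 0) stop("all-zero root partials");
  double lik = arma::accu(L % L) / s;   // sum_i (L_i/s) * L_i
  return List::create(_["loglik"] = std::log(lik) + logscale(root),
                      _["root_partial"] = L,
                      _["log_scale"] = logscale(root));
}

// Down-pass partials for every node (for marginal reconstruction).
// Returns k x (ntip+n_node) scaled partials and per-node cumulative log
// scale F, so the true partial of node v is part[,v] * exp(F[v]).
// [[Rcpp::export]]
List cpp_down_partials(const arma::imat& edge, const arma::vec& len,
                       const arma::mat& tip_partials, const arma::mat& Q,
                       int n_node) {
  const int ntip = tip_partials.n_cols;
  const int k = tip_partials.n_rows;
  const int ntot = ntip + n_node;
  arma::mat part(k, ntot, arma::fill::ones);
  part.cols(0, ntip - 1) = tip_partials;
  arma::vec logscale(ntot, arma::fill::zeros);
  arma::ivec nseen(ntot, arma::fill::zeros);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    arma::mat P = arma::expmat(Q * len(e));
    part.col(par) %= P * part.col(ch);
    logscale(par) += logscale(ch);
    if (++nseen(par) == 2) {
      double m = part.col(par).max();
      if (m > 0) { part.col(par) /= m; logscale(par) += std::log(m); }
    }
  }
  return List::create(_["partials"] = part, _["log_scale"] = logscale);
}

// Sum of sister-clade differences for many trait vectors at once.
// Nodal values are the unweighted mean of the two daughter values; the
// statistic is the sum over internal nodes of |left - right|.
// edge is postorder as above; vals: ntip x nrep.
// [[Rcpp::export]]
arma::rowvec cpp_sister_diff_sum(const arma::imat& edge,
                                 const arma::mat& vals, int n_node) {
  const int ntip = vals.n_rows;
  const int nrep = vals.n_cols;
  const int ntot = ntip + n_node;
  arma::mat nodeval(ntot, nrep, arma::fill::zeros);
  nodeval.rows(0, ntip - 1) = vals;
  arma::mat first(ntot, nrep, arma::fill::zeros);
  arma::ivec nseen(ntot, arma::fill::zeros);
  arma::rowvec d(nrep, arma::fill::zeros);
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    if (nseen(par) == 0) {
      first.row(par) = nodeval.row(ch);
      nseen(par) = 1;
    } else {
      d += arma::abs(first.row(par) - nodeval.row(ch));
      nodeval.row(par) = (first.row(par) + nodeval.row(ch)) / 2.0;
    }
  }
  return d;
}
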