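// Felsenstein pruning over the 61 sense codons, with per-edge mixtures of
// rate classes.  The rate matrix is reversible, so transition probabilities
// are obtained from the eigendecomposition of the pi^(1/2)-symmetrized
// matrix, which is numerically stable at large branch lengths.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// P(t) = D^{ -1/2 } V exp(lam t) V' D^{ 1/2 },  D = diag(pi)
arma::mat trans_prob(const arma::mat& A, const arma::mat& B,
                     const arma::vec& lam, double t) {
  arma::mat P = A * arma::diagmat(arma::exp(lam * t)) * B;
  // clamp tiny negative round-off
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

} // namespace

// edge: postorder edge matrix (ape node numbering, 1-based; tips 1..n_tip,
//   root n_tip+1).  tip_states: n_tip x npat, codon index 1..61, 0 = missing.
// eig: list of rate classes, each list(A, B, lam) with
//   A = diag(1/sqrt(pi)) V, B = V' diag(sqrt(pi)).
// edge_class_w: nedge x nclass mixture weights (rows sum to 1).
// [[Rcpp::export(name = ".cpp_prune_loglik")]]
List cpp_prune_loglik(const arma::imat& edge, const arma::vec& edge_length,
                      int n_tip, const arma::imat& tip_states,
                      const arma::vec& weights, const arma::vec& pi,
                      List eig, const arma::mat& edge_class_w) {
  const int ns = pi.n_elem;            // 61 states
  const int npat = tip_states.n_cols;
  const int nedge = edge.n_rows;
  const int nnode = 2 * n_tip;         // upper bound on ape node ids + 1
  const int nclass = eig.size();

  std::vector<arma::mat> A(nclass), B(nclass);
  std::vector<arma::vec> lam(nclass);
  for (int c = 0; c < nclass; ++c) {
    List e = eig[c];
    A[c] = as<arma::mat>(e["A"]);
    B[c] = as<arma::mat>(e["B"]);
    lam[c] = as<arma::vec>(e["lam"]);
  }

  std::vector<arma::mat> part(nnode + 1);
  arma::rowvec logscale(npat, arma::fill::zeros);

  // For few site patterns it is cheaper to apply A diag(e^{lam t}) B as
  // matrix-vector products than to form P explicitly.
  const bool matvec = npat < ns;

  for (int e = 0; e < nedge; ++e) {
    const int parent = edge(e, 0), child = edge(e, 1);
    arma::mat contrib(ns, npat, arma::fill::zeros);
    if (matvec) {
      arma::mat X(ns, npat);
      if (child <= n_tip) {
        for (int j = 0; j < npat; ++j) {
          const int s = tip_states(child - 1, j);
          if (s > 0) { X.col(j).zeros(); X(s - 1, j) = 1.0; }
          else X.col(j).ones();
        }
      } else {
        X = part[child];
      }
      for (int c = 0; c < nclass; ++c) {
        const double w = edge_class_w(e, c);
        if (w <= 0.0) continue;
        arma::mat Y = B[c] * X;
        Y.each_col() %= arma::exp(lam[c] * edge_length(e));
        contrib += w * (A[c] * Y);
      }
      contrib.transform([](double x) { return x < 0.0 ? 0.0 : x; });
      if (child > n_tip) part[child].reset();
    } else {
      arma::mat P(ns, ns, arma::fill::zeros);
      for (int c = 0; c < nclass; ++c) {
        const double w = edge_class_w(e, c);
        if (w > 0.0) P += w * trans_prob(A[c], B[c], lam[c], edge_length(e));
      }
      if (child <= n_tip) {
        const arma::colvec rowsum = arma::sum(P, 1);
        for (int j = 0; j < npat; ++j) {
          const int s = tip_states(child - 1, j);
          contrib.col(j) = (s > 0) ? P.col(s - 1) : rowsum;
        }
      } else {
        contrib = P * part[child];
        part[child].reset();
      }
    }
    if (part[parent].is_empty()) {
      part[parent] = contrib;
    } else {
      part[parent] %= contrib;
    }
    // rescale to avoid underflow on deep trees
    for (int j = 0; j < npat; ++j) {
      const double m = part[parent].col(j).max();
      if (m > 0.0 && m < 1e-120) {
        part[parent].col(j) /= m;
        logscale(j) += std::log(m);
      }
    }
  }

  const int root = n_tip + 1;
  arma::rowvec site_ll(npat);
  for (int j = 0; j < npat; ++j) {
    const double lik = arma::dot(pi, part[root].col(j));
    site_ll(j) = (lik > 0.0 ? std::log(lik) : -1e300) + logscale(j);
  }
  const double total = arma::dot(site_ll, weights.t());
  return List::create(_["loglik"] = total,
                      _["pattern_loglik"] = NumericVector(site_ll.begin(), site_ll.end()));
}
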