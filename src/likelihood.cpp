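// Pruning-likelihood engine shared by the codon (61-state) and nucleotide
// (4-state) acceleration tests.  Transition probabilities come from the
// eigendecomposition of the pi-symmetrized generator of a reversible chain;
// scaling-and-squaring (arma::expmat) is the fallback when the
// symmetrization is ill-conditioned.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat trans_mat_internal(const arma::mat& G, const arma::vec& pi) {
  const arma::uword k = G.n_rows;
  bool ok = pi.min() > 0;
  if (ok) {
    arma::vec sq = arma::sqrt(pi);
    arma::mat S = G;
    for (arma::uword i = 0; i < k; ++i)
      for (arma::uword j = 0; j < k; ++j)
        S(i, j) = G(i, j) * sq(i) / sq(j);
    // reversibility => S symmetric up to round-off
    double asym = arma::abs(S - S.t()).max();
    double scale = arma::abs(S).max();
    if (scale > 0 && asym / scale < 1e-8) {
      S = 0.5 * (S + S.t());
      arma::vec eval;
      arma::mat evec;
      if (arma::eig_sym(eval, evec, S)) {
        arma::mat P(k, k);
        arma::mat E = evec * arma::diagmat(arma::exp(eval)) * evec.t();
        for (arma::uword i = 0; i < k; ++i)
          for (arma::uword j = 0; j < k; ++j)
            P(i, j) = E(i, j) * sq(j) / sq(i);
        // clamp numerical negatives, renormalize rows
        P.transform([](double x) { return x < 0 ? 0.0 : x; });
        arma::vec rs = arma::sum(P, 1);
        P.each_col() /= rs;
        return P;
      }
    }
  }
  arma::mat P = arma::expmat(G);
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// [[Rcpp::export(name = ".transMatCpp")]]
arma::mat transMatCpp(const arma::mat& G, const arma::vec& pi) {
  return trans_mat_internal(G, pi);
}

// Batch transition matrices for branch generators s_i * A + n_i * B (B may
// be 0 x 0 to mean "no second component").  Returns a k x k x length(s)
// cube.  Used by the fitting engine so per-evaluation work stays in C++.
// [[Rcpp::export(name = ".batchTransMatCpp")]]
arma::cube batchTransMatCpp(const arma::mat& A, const arma::mat& B,
                            const arma::vec& s, const arma::vec& n,
                            const arma::vec& pi) {
  const arma::uword k = A.n_rows;
  const arma::uword m = s.n_elem;
  const bool haveB = B.n_rows == k;
  arma::cube P(k, k, m);
  for (arma::uword i = 0; i < m; ++i) {
    arma::mat G = s(i) * A;
    if (haveB && n(i) != 0) G += n(i) * B;
    P.slice(i) = trans_mat_internal(G, pi);
  }
  return P;
}

// Felsenstein pruning over site patterns.
//
// tipStates: ntip x npat integer matrix, 1-based states, 0 = missing.
// edge:      nedge x 2 (parent, child), 1-based node indices, tips are
//            1..ntip, internal nodes ntip+1..nnode; rows in postorder
//            (every child row precedes its parent's own child row).
// P:         k x k x nedge cube, P.slice(e) aligned with edge row e.
// pi:        stationary frequencies at the root.
// weights:   pattern multiplicities.
// root:      1-based index of the root node.
// [[Rcpp::export(name = ".pruneLoglikCpp")]]
double pruneLoglikCpp(const IntegerMatrix& tipStates,
                      const IntegerMatrix& edge,
                      const arma::cube& P,
                      const arma::vec& pi,
                      const arma::vec& weights,
                      int nnode,
                      int root) {
  const int ntip = tipStates.nrow();
  const int npat = tipStates.ncol();
  const int k = pi.n_elem;
  const int nedge = edge.nrow();

  std::vector<arma::mat> L(nnode + 1);
  std::vector<bool> seen(nnode + 1, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    arma::mat contrib(k, npat);
    if (ch <= ntip) {
      // tip partials are indicator columns: P * L is a column gather
      for (int s = 0; s < npat; ++s) {
        int st = tipStates(ch - 1, s);
        if (st == NA_INTEGER || st == 0)
          contrib.col(s).ones();  // rows of P sum to 1
        else
          contrib.col(s) = P.slice(e).col(st - 1);
      }
    } else {
      contrib = P.slice(e) * L[ch];
      L[ch].reset();
    }
    if (!seen[par]) {
      L[par] = contrib;
      seen[par] = true;
    } else {
      L[par] %= contrib;
      // rescale to avoid underflow
      arma::rowvec mx = arma::max(L[par], 0);
      for (int s = 0; s < npat; ++s) {
        if (mx(s) > 0 && mx(s) < 1e-200) {
          L[par].col(s) /= mx(s);
          logscale(s) += std::log(mx(s));
        }
      }
    }
  }

  arma::rowvec site = pi.t() * L[root];
  double ll = 0.0;
  for (int s = 0; s < npat; ++s) {
    double v = site(s);
    if (v <= 0) return -std::numeric_limits<double>::infinity();
    ll += weights(s) * (std::log(v) + logscale(s));
  }
  return ll;
}
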