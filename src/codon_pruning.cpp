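// Felsenstein pruning over codon states with per-branch rate classes.
//
// The generator Q is time-reversible, so P(t) = A diag(exp(lambda t)) B with
// A = D^{-1/2} U, B = U' D^{1/2} from the symmetric eigenproblem of
// D^{1/2} Q D^{-1/2} (D = diag(pi)).  The eigendecomposition is done once per
// (kappa, omega) in R; this kernel only rescales per branch, which is what
// makes joint ML over branch lengths affordable.
//
// Branch-length gradients use the standard two-pass scheme: a postorder pass
// storing per-edge messages M_e = P_e L_child and per-node partials, then a
// preorder pass propagating the "rest of tree" partial V_e.  Per-site scale
// factors cancel in the ratio dot(V_e, dP/dt L_c) / dot(V_e, M_e).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static mat branch_P(const mat& A, const mat& B, const vec& lam, double t) {
  vec e = exp(lam * t);
  mat P = (A * diagmat(e)) * B;
  P.for_each([](double& x) { if (x < 0.0) x = 0.0; });
  return P;
}

static mat branch_dP(const mat& A, const mat& B, const vec& lam, double t) {
  vec e = lam % exp(lam * t);
  return (A * diagmat(e)) * B;
}

// tip_states: ntip x npat, 1-based codon state or 0 = missing.
// edge: nedge x 2 (parent, child), 1-based ape node ids, postorder
//       (every child edge appears before its parent's edge).
// eclass: 0 = background eigensystem, 1 = foreground.
// [[Rcpp::export]]
Rcpp::List cpp_codon_loglik(const arma::imat& tip_states,
                            const arma::vec& weights,
                            const arma::imat& edge,
                            const arma::vec& edge_len,
                            const arma::ivec& eclass,
                            const arma::mat& A0, const arma::mat& B0, const arma::vec& lam0,
                            const arma::mat& A1, const arma::mat& B1, const arma::vec& lam1,
                            const arma::vec& pi,
                            int n_node,
                            bool want_grad) {
  const int S = pi.n_elem;
  const int npat = tip_states.n_cols;
  const int ntip = tip_states.n_rows;
  const int nedge = edge.n_rows;
  const int root = ntip; // 0-based id of ape root node (ntip + 1 in R)

  // per-node partials for internal nodes only (tips are delta vectors)
  std::vector<mat> L(n_node);
  std::vector<rowvec> logscale(n_node);
  std::vector<bool> started(n_node, false);
  std::vector<mat> M(nedge);      // per-edge message P_e L_child
  std::vector<mat> Pmat(nedge);
  // children edges per node (for the preorder pass)
  std::vector<std::vector<int>> child_edges(n_node);

  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    child_edges[p].push_back(e);
    const mat& A = eclass[e] ? A1 : A0;
    const mat& B = eclass[e] ? B1 : B0;
    const vec& lm = eclass[e] ? lam1 : lam0;
    mat P = branch_P(A, B, lm, edge_len[e]);

    mat Me(S, npat);
    if (c < ntip) {
      for (int s = 0; s < npat; ++s) {
        int st = tip_states(c, s);
        if (st <= 0) Me.col(s).ones();
        else Me.col(s) = P.col(st - 1);
      }
    } else {
      // child subtree is complete (postorder): rescale its partial first
      rowvec mx = max(L[c], 0);
      mx.for_each([](double& x) { if (x <= 0.0) x = 1.0; });
      L[c].each_row() /= mx;
      logscale[c] += log(mx);
      Me = P * L[c];
    }
    if (!started[p]) {
      L[p] = Me;
      logscale[p] = (c < ntip) ? rowvec(npat, fill::zeros) : logscale[c];
      started[p] = true;
    } else {
      L[p] %= Me;
      if (c >= ntip) logscale[p] += logscale[c];
    }
    if (want_grad) { M[e] = std::move(Me); Pmat[e] = std::move(P); }
  }

  rowvec siteL = pi.t() * L[root];
  double lnL = 0.0;
  for (int s = 0; s < npat; ++s) {
    double v = siteL[s];
    lnL += weights[s] * (std::log(v > 0 ? v : DBL_MIN) + logscale[root][s]);
  }

  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loglik") = lnL);
  if (!want_grad) return out;

  // preorder pass: V_e = U_p .% prod_{siblings} M_sib ; U_c = P_e' V_e
  vec grad(nedge, fill::zeros);
  std::vector<mat> U(n_node);
  U[root] = repmat(pi, 1, npat);

  for (int e = nedge - 1; e >= 0; --e) { // reverse postorder = preorder
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    const std::vector<int>& sibs = child_edges[p];
    mat V = U[p];
    for (size_t k = 0; k < sibs.size(); ++k)
      if (sibs[k] != e) V %= M[sibs[k]];

    // site likelihood in this edge's scaling
    rowvec denom(npat);
    for (int s = 0; s < npat; ++s) denom[s] = dot(V.col(s), M[e].col(s));

    const mat& A = eclass[e] ? A1 : A0;
    const mat& B = eclass[e] ? B1 : B0;
    const vec& lm = eclass[e] ? lam1 : lam0;
    mat dP = branch_dP(A, B, lm, edge_len[e]);
    mat G(S, npat);
    if (c < ntip) {
      for (int s = 0; s < npat; ++s) {
        int st = tip_states(c, s);
        if (st <= 0) G.col(s).zeros(); // d/dt of all-ones message is 0
        else G.col(s) = dP.col(st - 1);
      }
    } else {
      G = dP * L[c];
    }
    double g = 0.0;
    for (int s = 0; s < npat; ++s) {
      double d = denom[s];
      if (d > 0) g += weights[s] * dot(V.col(s), G.col(s)) / d;
    }
    grad[e] = g;

    if (c >= ntip) {
      mat Uc = Pmat[e].t() * V;
      rowvec mx = max(Uc, 0);
      mx.for_each([](double& x) { if (x <= 0.0) x = 1.0; });
      Uc.each_row() /= mx;
      U[c] = std::move(Uc);
    }
  }
  out["grad"] = grad;
  return out;
}
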