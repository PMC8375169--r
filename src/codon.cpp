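// MG94xREV codon-model numerics: rate matrices, transition probabilities via
// symmetrized eigendecomposition, Felsenstein pruning over the 61 sense
// codons, and per-edge likelihood contexts used by the coordinate-ascent
// optimizers. All state indices are 0-based codon indices into the caller's
// sense-codon table; -1 marks missing data (gap/ambiguity).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Build the MG94xREV generator. `changes` columns: i, j, pair (0..5 GTR
// exchangeability index), pos (0..2), target_nt (0..3), syn (0/1); one row per
// ordered pair of codons differing at exactly one position. rho has 6 entries
// (AG entry fixed to 1 by the caller). pinuc is 3x4 position-specific
// nucleotide frequencies. s and n scale synonymous / non-synonymous changes.
// [[Rcpp::export]]
arma::mat mg94_q_cpp(const arma::imat& changes, const arma::vec& rho,
                     const arma::mat& pinuc, double s, double n) {
  arma::mat Q(61, 61, arma::fill::zeros);
  const int m = changes.n_rows;
  for (int k = 0; k < m; ++k) {
    int i = changes(k, 0), j = changes(k, 1);
    double rate = rho(changes(k, 2)) * pinuc(changes(k, 3), changes(k, 4));
    rate *= changes(k, 5) ? s : n;
    Q(i, j) = rate;
  }
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

static arma::mat pmat_from_q(const arma::mat& Q, const arma::vec& pi) {
  // reversible Q: D^{1/2} Q D^{-1/2} is symmetric (D = diag(pi))
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;        // row i scaled by sqrt(pi_i)
  B.each_row() /= sq.t();    // col j scaled by 1/sqrt(pi_j)
  B = 0.5 * (B + B.t());     // symmetrize against rounding
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, B);
  arma::mat P = evec * arma::diagmat(arma::exp(eval)) * evec.t();
  P.each_col() /= sq;
  P.each_row() %= sq.t();
  P.elem(arma::find(P < 0)).zeros();  // clip tiny negative round-off
  // renormalize rows to sum exactly 1
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// Cached spectral form of a reversible generator: P(t) = A exp(L t) Bi.
// [[Rcpp::export]]
List mg94_eig_cpp(const arma::imat& changes, const arma::vec& rho,
                  const arma::mat& pinuc, const arma::vec& pi,
                  double s, double n) {
  arma::mat Q = mg94_q_cpp(changes, rho, pinuc, s, n);
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;
  B.each_row() /= sq.t();
  B = 0.5 * (B + B.t());
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, B);
  arma::mat A = evec;
  A.each_col() /= sq;
  arma::mat Bi = evec.t();
  Bi.each_row() %= sq.t();
  return List::create(_["A"] = A, _["Bi"] = Bi, _["lambda"] = eval);
}

static arma::mat pmat_from_eig(const arma::mat& A, const arma::mat& Bi,
                               const arma::vec& lambda, double t) {
  arma::mat P = A * arma::diagmat(arma::exp(lambda * t)) * Bi;
  P.elem(arma::find(P < 0)).zeros();
  arma::vec rs = arma::sum(P, 1);
  P.each_col() /= rs;
  return P;
}

// [[Rcpp::export]]
arma::cube pmats_from_eig_cpp(const arma::mat& A, const arma::mat& Bi,
                              const arma::vec& lambda, const arma::vec& tvec) {
  const int E = tvec.n_elem;
  arma::cube P(61, 61, E);
  for (int e = 0; e < E; ++e) P.slice(e) = pmat_from_eig(A, Bi, lambda, tvec(e));
  return P;
}

// [[Rcpp::export]]
double edge_loglik_eig_cpp(const arma::mat& S, const arma::mat& D,
                           const arma::vec& logscale, const arma::vec& weights,
                           const arma::mat& A, const arma::mat& Bi,
                           const arma::vec& lambda, double t) {
  arma::mat P = pmat_from_eig(A, Bi, lambda, t);
  arma::vec site = arma::sum(S % (D * P.t()), 1);
  double ll = 0.0;
  for (arma::uword p = 0; p < site.n_elem; ++p)
    ll += weights(p) * (std::log(site(p)) + logscale(p));
  return ll;
}

// [[Rcpp::export]]
arma::mat mg94_pmat_cpp(const arma::imat& changes, const arma::vec& rho,
                        const arma::mat& pinuc, const arma::vec& pi,
                        double s, double n) {
  return pmat_from_q(mg94_q_cpp(changes, rho, pinuc, s, n), pi);
}

// [[Rcpp::export]]
arma::cube mg94_pmats_cpp(const arma::imat& changes, const arma::vec& rho,
                          const arma::mat& pinuc, const arma::vec& pi,
                          const arma::vec& svec, const arma::vec& nvec) {
  const int E = svec.n_elem;
  arma::cube P(61, 61, E);
  for (int e = 0; e < E; ++e)
    P.slice(e) = pmat_from_q(mg94_q_cpp(changes, rho, pinuc, svec(e), nvec(e)), pi);
  return P;
}

// Postorder pruning. patterns: ntip x npat integer matrix of codon states
// (-1 = missing). edges: E x 2 (parent, child), 0-based node ids, tips are
// 0..ntip-1, listed in postorder (children before parents). Pcube slice e is
// the transition matrix of edge e. Returns total log-likelihood with the
// stationary distribution placed at the root node.
// [[Rcpp::export]]
double prune_loglik_cpp(const arma::imat& patterns, const arma::vec& weights,
                        const arma::imat& edges, const arma::cube& Pcube,
                        const arma::vec& pi, int nnode, int root) {
  const int npat = patterns.n_cols;
  const int ntip = patterns.n_rows;
  const int E = edges.n_rows;
  // down[v]: npat x 61 partial likelihoods; logscale[v]: npat
  std::vector<arma::mat> down(nnode);
  std::vector<arma::vec> lsc(nnode, arma::vec(npat, arma::fill::zeros));
  for (int v = 0; v < ntip; ++v) {
    down[v].zeros(npat, 61);
    for (int p = 0; p < npat; ++p) {
      int st = patterns(v, p);
      if (st < 0) down[v].row(p).ones();
      else down[v](p, st) = 1.0;
    }
  }
  for (int u = ntip; u < nnode; ++u) down[u].ones(npat, 61);

  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    down[u] %= down[v] * Pcube.slice(e).t();
    lsc[u] += lsc[v];
    // rescale rows that got small
    arma::vec mx = arma::max(down[u], 1);
    for (int p = 0; p < npat; ++p) {
      if (mx(p) > 0 && mx(p) < 1e-200) {
        down[u].row(p) /= mx(p);
        lsc[u](p) += std::log(mx(p));
      }
    }
  }
  arma::vec site = down[root] * pi;
  double ll = 0.0;
  for (int p = 0; p < npat; ++p)
    ll += weights(p) * (std::log(site(p)) + lsc[root](p));
  return ll;
}

// Full postorder pass caching per-edge contributions: contrib[e] is the
// factor edge e multiplies into its parent's down partial, with its own
// per-pattern log scale. Supports exact incremental per-edge optimization
// sweeps driven from R.
// [[Rcpp::export]]
List down_pass_cpp(const arma::imat& patterns, const arma::imat& edges,
                   const arma::cube& Pcube, int nnode) {
  const int npat = patterns.n_cols;
  const int ntip = patterns.n_rows;
  const int E = edges.n_rows;
  arma::cube down(npat, 61, nnode);
  arma::mat dscale(npat, nnode, arma::fill::zeros);
  arma::cube contrib(npat, 61, E);
  arma::mat cscale(npat, E, arma::fill::zeros);
  for (int v = 0; v < ntip; ++v) {
    down.slice(v).zeros();
    for (int p = 0; p < npat; ++p) {
      int st = patterns(v, p);
      if (st < 0) down.slice(v).row(p).ones();
      else down(p, st, v) = 1.0;
    }
  }
  for (int u = ntip; u < nnode; ++u) down.slice(u).ones();
  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    contrib.slice(e) = down.slice(v) * Pcube.slice(e).t();
    cscale.col(e) = dscale.col(v);
    down.slice(u) %= contrib.slice(e);
    dscale.col(u) += cscale.col(e);
    arma::vec mx = arma::max(down.slice(u), 1);
    for (int p = 0; p < npat; ++p) {
      if (mx(p) > 0 && mx(p) < 1e-200) {
        down.slice(u).row(p) /= mx(p);
        dscale(p, u) += std::log(mx(p));
      }
    }
  }
  return List::create(_["down"] = down, _["dscale"] = dscale,
                      _["contrib"] = contrib, _["cscale"] = cscale);
}

// Likelihood context of a single edge: S (npat x 61) is the joint partial of
// everything on the parent side of the edge (stationary distribution
// included), D (npat x 61) the partial below the child. For any replacement
// transition matrix P on this edge the site likelihood is
// rowsum(S % (D P')), up to exp(logscale).
// [[Rcpp::export]]
List edge_context_cpp(const arma::imat& patterns, const arma::imat& edges,
                      const arma::cube& Pcube, const arma::vec& pi,
                      int nnode, int root, int target_edge) {
  const int npat = patterns.n_cols;
  const int ntip = patterns.n_rows;
  const int E = edges.n_rows;
  std::vector<arma::mat> down(nnode), contrib(E);
  std::vector<arma::vec> lsc(nnode, arma::vec(npat, arma::fill::zeros));
  for (int v = 0; v < ntip; ++v) {
    down[v].zeros(npat, 61);
    for (int p = 0; p < npat; ++p) {
      int st = patterns(v, p);
      if (st < 0) down[v].row(p).ones();
      else down[v](p, st) = 1.0;
    }
  }
  for (int u = ntip; u < nnode; ++u) down[u].ones(npat, 61);
  for (int e = 0; e < E; ++e) {
    int u = edges(e, 0), v = edges(e, 1);
    contrib[e] = down[v] * Pcube.slice(e).t();  // edge e's factor at node u
    down[u] %= contrib[e];
    lsc[u] += lsc[v];
    arma::vec mx = arma::max(down[u], 1);
    for (int p = 0; p < npat; ++p) {
      if (mx(p) > 0 && mx(p) < 1e-200) {
        down[u].row(p) /= mx(p);
        lsc[u](p) += std::log(mx(p));
      }
    }
  }
  // preorder: up[u] = partial of data outside the subtree of u, seen from u,
  // with pi placed at the root. up[root] = pi (as a row).
  std::vector<arma::mat> up(nnode);
  std::vector<arma::vec> upsc(nnode, arma::vec(npat, arma::fill::zeros));
  up[root].set_size(npat, 61);
  up[root].each_row() = pi.t();
  int tu = edges(target_edge, 0), tv = edges(target_edge, 1);
  arma::mat S;
  arma::vec Ssc;
  for (int e = E - 1; e >= 0; --e) {  // reverse postorder = preorder
    int u = edges(e, 0), v = edges(e, 1);
    // S_e = up[u] % (down[u] without edge e's contribution)
    arma::mat Se = up[u] % (down[u] / contrib[e]);
    // down[u]/contrib can produce 0/0 when contrib underflowed; guard
    Se.replace(arma::datum::nan, 0.0);
    arma::vec sc = upsc[u] + lsc[u] - lsc[v];
    if (e == target_edge) { S = Se; Ssc = sc; break; }
    up[v] = Se * Pcube.slice(e);
    upsc[v] = sc;
    arma::vec mx = arma::max(up[v], 1);
    for (int p = 0; p < npat; ++p) {
      if (mx(p) > 0 && mx(p) < 1e-200) {
        up[v].row(p) /= mx(p);
        upsc[v](p) += std::log(mx(p));
      }
    }
  }
  (void)tu; (void)tv;
  return List::create(_["S"] = S, _["D"] = down[edges(target_edge, 1)],
                      _["logscale"] = Ssc + lsc[edges(target_edge, 1)]);
}

// [[Rcpp::export]]
double edge_loglik_cpp(const arma::mat& S, const arma::mat& D,
                       const arma::vec& logscale, const arma::vec& weights,
                       const arma::mat& P) {
  arma::vec site = arma::sum(S % (D * P.t()), 1);
  double ll = 0.0;
  for (arma::uword p = 0; p < site.n_elem; ++p)
    ll += weights(p) * (std::log(site(p)) + logscale(p));
  return ll;
}

// Evolve codon states down a tree: seq[root] ~ pi, child ~ P_e(parent,.)
// Returns ntip x nsites integer matrix. unif is a pre-drawn matrix of
// uniforms (nnode x nsites) so the caller controls the RNG stream.
// [[Rcpp::export]]
arma::imat sim_codon_cpp(const arma::imat& edges, const arma::cube& Pcube,
                         const arma::vec& pi, int nnode, int root, int ntip,
                         int nsites, const arma::mat& unif) {
  arma::imat states(nnode, nsites);
  // root draw from pi
  arma::vec cpi = arma::cumsum(pi);
  for (int s = 0; s < nsites; ++s) {
    double u = unif(root, s);
    int st = 0;
    while (st < 60 && u > cpi(st)) ++st;
    states(root, s) = st;
  }
  const int E = edges.n_rows;
  for (int e = E - 1; e >= 0; --e) {  // preorder
    int up = edges(e, 0), v = edges(e, 1);
    const arma::mat& P = Pcube.slice(e);
    for (int s = 0; s < nsites; ++s) {
      double u = unif(v, s);
      const int pst = states(up, s);
      double acc = 0.0;
      int st = 0;
      for (; st < 61; ++st) {
        acc += P(pst, st);
        if (u <= acc) break;
      }
      states(v, s) = st > 60 ? 60 : st;
    }
  }
  return states.rows(0, ntip - 1);
}
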