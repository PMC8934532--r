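// Pruning likelihood for site-class codon models on unrooted trees.
//
// The tree is passed as an edge list in postorder (every child appears
// before its parent).  Node ids are 0-based: tips 0..ntip-1 in the row
// order of the tip state matrix, internal nodes ntip..nnode-1, with `root`
// the node carrying the stationary distribution.  Branch lengths are in
// the *unscaled* time units of the eigendecompositions supplied in `eig`;
// the R layer owns the substitutions-per-codon rescaling.
//
// Site classes share branch lengths but may use different rate matrices on
// different edges (class_omega maps class x edge -> eigen index), which is
// how the foreground-branch model is expressed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat pmat_from_eigen(const arma::mat& U, const arma::mat& W,
                                 const arma::vec& lambda, double t) {
  // exp(Q*0) is exactly the identity; the eigen reconstruction would leave
  // O(eps) off-diagonal residue that turns impossible columns into tiny
  // positive likelihoods
  if (t == 0.0) return arma::eye(U.n_rows, U.n_rows);
  arma::mat P = U * arma::diagmat(arma::exp(lambda * t)) * W;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

static arma::mat qpmat_from_eigen(const arma::mat& U, const arma::mat& W,
                                  const arma::vec& lambda, double t) {
  // d/dt expm(Qt) = Q expm(Qt) = U diag(lambda exp(lambda t)) W
  return U * arma::diagmat(lambda % arma::exp(lambda * t)) * W;
}

// [[Rcpp::export(name = ".cpp_codon_loglik")]]
List cpp_codon_loglik(const arma::imat& tips,      // ntip x npat, 0-based, nstate = missing
                      const arma::vec& wts,        // npat pattern weights
                      const arma::imat& edge,      // nedge x 2 (parent, child), postorder
                      const int nnode,
                      const int root,
                      const arma::vec& tvec,       // nedge branch lengths (unscaled units)
                      const List& eig,             // list of list(U, W, lambda)
                      const arma::imat& class_omega, // nclass x nedge, 0-based eigen index
                      const arma::vec& class_p,    // nclass mixture weights
                      const arma::vec& pi,         // nstate root frequencies
                      const bool gradient) {
  const int ntip = tips.n_rows;
  const int npat = tips.n_cols;
  const int nedge = edge.n_rows;
  const int nclass = class_omega.n_rows;
  const int nstate = pi.n_elem;
  const int neig = eig.size();

  std::vector<arma::mat> Us(neig), Ws(neig);
  std::vector<arma::vec> Ls(neig);
  for (int k = 0; k < neig; ++k) {
    List ek = eig[k];
    Us[k] = as<arma::mat>(ek["U"]);
    Ws[k] = as<arma::mat>(ek["W"]);
    Ls[k] = as<arma::vec>(ek["lambda"]);
  }

  // P-matrix cache keyed by (eigen index, edge)
  std::vector<arma::mat> pcache((size_t)neig * nedge);
  std::vector<bool> phave((size_t)neig * nedge, false);
  auto getP = [&](int k, int e) -> const arma::mat& {
    size_t key = (size_t)k * nedge + e;
    if (!phave[key]) {
      pcache[key] = pmat_from_eigen(Us[k], Ws[k], Ls[k], tvec(e));
      phave[key] = true;
    }
    return pcache[key];
  };

  arma::mat class_site_ll(nclass, npat);          // log per-class site likelihoods
  arma::vec grad(nedge, arma::fill::zeros);
  // per-class storage for the gradient pass
  std::vector<arma::mat> down_store, msg_store;
  std::vector<arma::rowvec> scale_store;          // per node cumulative log scale
  // children edges per node
  std::vector<std::vector<int>> child_edges(nnode);
  for (int e = 0; e < nedge; ++e) child_edges[edge(e, 0)].push_back(e);

  arma::mat grad_cs;                              // nclass x npat site ll
  std::vector<std::vector<arma::mat>> all_msgs(nclass), all_downs(nclass);
  std::vector<std::vector<arma::rowvec>> all_scales(nclass);

  for (int c = 0; c < nclass; ++c) {
    std::vector<arma::mat> down(nnode);           // partials at internal nodes
    std::vector<arma::rowvec> sc(nnode, arma::rowvec(npat, arma::fill::zeros));
    std::vector<arma::mat> msgs(nedge);
    for (int n = ntip; n < nnode; ++n) down[n] = arma::mat(nstate, npat, arma::fill::ones);

    for (int e = 0; e < nedge; ++e) {
      const int par = edge(e, 0), ch = edge(e, 1);
      const arma::mat& P = getP(class_omega(c, e), e);
      arma::mat m(nstate, npat);
      if (ch < ntip) {
        for (int s = 0; s < npat; ++s) {
          int st = tips(ch, s);
          if (st >= nstate) m.col(s).ones();
          else m.col(s) = P.col(st);
        }
      } else {
        // rescale the child partial before propagating
        arma::rowvec mx = arma::max(down[ch], 0);
        mx.transform([](double x) { return x <= 0.0 ? 1.0 : x; });
        down[ch].each_row() /= mx;
        sc[ch] += arma::log(mx);
        m = P * down[ch];
        sc[ch] += arma::rowvec(npat, arma::fill::zeros); // no-op, clarity
      }
      down[par] %= m;
      sc[par] += sc[ch];
      if (gradient) msgs[e] = m;
    }
    arma::rowvec site = pi.t() * down[root];
    for (int s = 0; s < npat; ++s) {
      class_site_ll(c, s) = (site(s) > 0.0) ? std::log(site(s)) + sc[root](s)
                                            : -arma::datum::inf;
    }
    if (gradient) {
      all_msgs[c] = std::move(msgs);
      all_downs[c] = std::move(down);
      all_scales[c] = std::move(sc);
    }
  }

  // total log-likelihood via per-site log-sum-exp over classes
  arma::rowvec site_ll(npat);
  for (int s = 0; s < npat; ++s) {
    double mx = -arma::datum::inf;
    for (int c = 0; c < nclass; ++c) {
      double v = class_site_ll(c, s) + std::log(class_p(c));
      if (v > mx) mx = v;
    }
    if (!std::isfinite(mx)) { site_ll(s) = -arma::datum::inf; continue; }
    double acc = 0.0;
    for (int c = 0; c < nclass; ++c)
      acc += std::exp(class_site_ll(c, s) + std::log(class_p(c)) - mx);
    site_ll(s) = mx + std::log(acc);
  }
  double loglik = arma::dot(wts, site_ll.t());

  if (gradient && std::isfinite(loglik)) {
    // Preorder pass computing "above" partials, per class.
    for (int c = 0; c < nclass; ++c) {
      std::vector<arma::mat>& msgs = all_msgs[c];
      std::vector<arma::mat>& down = all_downs[c];
      std::vector<arma::rowvec>& sc = all_scales[c];
      std::vector<arma::mat> above(nnode);        // B_v matrices
      std::vector<arma::rowvec> asc(nnode, arma::rowvec(npat, arma::fill::zeros));
      above[root] = arma::repmat(pi, 1, npat);
      for (int e = nedge - 1; e >= 0; --e) {      // reverse postorder = preorder
        const int par = edge(e, 0), ch = edge(e, 1);
        // A_e = above[par] * prod of sibling messages
        arma::mat A = above[par];
        arma::rowvec a = asc[par];
        for (int e2 : child_edges[par]) {
          if (e2 == e) continue;
          A %= msgs[e2];
          a += sc[edge(e2, 1)];
        }
        // gradient contribution for this edge
        const int k = class_omega(c, e);
        arma::mat QP = qpmat_from_eigen(Us[k], Ws[k], Ls[k], tvec(e));
        arma::mat g(nstate, npat);
        if (ch < ntip) {
          for (int s = 0; s < npat; ++s) {
            int st = tips(ch, s);
            if (st >= nstate) g.col(s).zeros();   // rows of Q sum to 0
            else g.col(s) = QP.col(st);
          }
        } else {
          g = QP * down[ch];
        }
        arma::rowvec num = arma::sum(A % g, 0);
        arma::rowvec chs = (ch < ntip) ? arma::rowvec(npat, arma::fill::zeros) : sc[ch];
        for (int s = 0; s < npat; ++s) {
          if (!std::isfinite(site_ll(s))) continue;
          // d lnL/dt = sum_c p_c dL_c/dt / L_s with all scales restored
          double logabs = a(s) + chs(s) - site_ll(s) + std::log(class_p(c));
          grad(e) += wts(s) * num(s) * std::exp(logabs);
        }
        if (ch >= ntip) {                         // propagate above partial
          const arma::mat& P = getP(k, e);
          above[ch] = P.t() * A;
          arma::rowvec mx = arma::max(above[ch], 0);
          mx.transform([](double x) { return x <= 0.0 ? 1.0 : x; });
          above[ch].each_row() /= mx;
          asc[ch] = a + arma::log(mx);
        }
      }
    }
  }

  return List::create(
    _["loglik"] = loglik,
    _["class_site_ll"] = class_site_ll,
    _["site_ll"] = site_ll,
    _["grad"] = gradient ? wrap(grad) : R_NilValue
  );
}
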