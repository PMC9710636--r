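// E-step kernel: Felsenstein pruning (inside/outside) and the
// eigendecomposition integrals for expected dwell times and transition
// counts, for all clusters of a mixture in one call. Trees use 1-based
// post-order node indices (children before parents, root last) as in the R
// gcevo_tree structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// I_pq(t) = (exp(l_p t) - exp(l_q t)) / (l_p - l_q), with the limit
// t * exp(l_p t) for (near-)degenerate pairs
static mat exp_integral(const vec& values, double t) {
  const uword s = values.n_elem;
  vec el = exp(values * t);
  mat I(s, s);
  for (uword p = 0; p < s; ++p) {
    for (uword q = 0; q < s; ++q) {
      double den = values[p] - values[q];
      if (std::abs(den) < 1e-9 * std::max(1.0, std::abs(values[p]))) {
        I(p, q) = t * el[p];
      } else {
        I(p, q) = (el[p] - el[q]) / den;
      }
    }
  }
  return I;
}

static mat transition(const vec& values, const mat& U, const mat& Uinv,
                      double t) {
  mat P = U * diagmat(exp(values * t)) * Uinv;
  P.transform([](double x) { return x < 0 ? 0.0 : x; });
  P.each_col() /= sum(P, 1);
  return P;
}

// [[Rcpp::export(name = ".em_estep_kernel")]]
Rcpp::List em_estep_kernel(const arma::imat& D,        // n_tip x L, states 0..lmax
                           const arma::ivec& parent,   // 1-based, 0 at root
                           const arma::imat& children, // n_node x 2, 0 at tips
                           const arma::ivec& tip_row,  // node -> row of D (1-based, 0 if internal)
                           const arma::vec& brlen,     // 0 at root
                           const Rcpp::List& clusters, // per k: values, U, Uinv, R, pi
                           const arma::vec& phi,
                           const arma::vec& weights,
                           bool want_moments) {
  const uword n_node = parent.n_elem;
  const uword L = D.n_cols;
  const uword K = clusters.size();
  const uword root = n_node - 1;

  std::vector<cube> insideK(K), msgK(K), Pk(K);
  std::vector<vec> cumlsK(K);
  mat ll(L, K);
  uword s = 0;

  for (uword k = 0; k < K; ++k) {
    Rcpp::List cl = clusters[k];
    vec values = cl["values"];
    mat U = cl["U"], Uinv = cl["Uinv"];
    vec pi = cl["pi"];
    s = values.n_elem;
    cube P(s, s, n_node, fill::zeros);
    for (uword m = 0; m < n_node - 1; ++m) {
      P.slice(m) = transition(values, U, Uinv, brlen[m]);
    }
    cube inside(s, L, n_node), msg(s, L, n_node, fill::zeros);
    vec cumls(L, fill::zeros);
    std::vector<vec> cum(n_node);
    for (uword m = 0; m < n_node; ++m) {
      if (children(m, 0) == 0) {          // tip
        mat ind(s, L, fill::zeros);
        uword row = tip_row[m] - 1;
        for (uword l = 0; l < L; ++l) ind(D(row, l), l) = 1.0;
        inside.slice(m) = ind;
        cum[m] = vec(L, fill::zeros);
        // msg = P[, states]
        mat& Ms = msg.slice(m);
        for (uword l = 0; l < L; ++l) Ms.col(l) = P.slice(m).col(D(row, l));
      } else {
        uword c1 = children(m, 0) - 1, c2 = children(m, 1) - 1;
        mat raw = msg.slice(c1) % msg.slice(c2);
        rowvec sc = sum(raw, 0);
        raw.each_row() /= sc;
        inside.slice(m) = raw;
        cum[m] = cum[c1] + cum[c2] + log(sc.t());
        if (m < root) msg.slice(m) = P.slice(m) * raw;
      }
    }
    ll.col(k) = log((pi.t() * inside.slice(root)).t()) + cum[root];
    insideK[k] = std::move(inside);
    msgK[k] = std::move(msg);
    Pk[k] = std::move(P);
    cumlsK[k] = cum[root];
  }

  // responsibilities via log-sum-exp
  mat logpost = ll;
  for (uword k = 0; k < K; ++k) logpost.col(k) += std::log(phi[k]);
  vec mx = max(logpost, 1);
  mat gamma = exp(logpost.each_col() - mx);
  vec rs = sum(gamma, 1);
  gamma.each_col() /= rs;
  vec family_loglik = mx + log(rs);
  double loglik = dot(weights, family_loglik);

  Rcpp::List statsOut(K);
  mat n_root(K, s, fill::zeros);
  if (want_moments) {
    for (uword k = 0; k < K; ++k) {
      Rcpp::List cl = clusters[k];
      vec values = cl["values"];
      mat U = cl["U"], Uinv = cl["Uinv"], R = cl["R"];
      vec pi = cl["pi"];
      const cube& inside = insideK[k];
      const cube& msg = msgK[k];
      const cube& P = Pk[k];
      vec gw = gamma.col(k) % weights;

      // outside pass
      cube out(s, L, n_node);
      out.slice(root) = repmat(pi, 1, L);
      for (uword m = n_node; m-- > 0;) {
        if (children(m, 0) == 0) continue;
        uword c1 = children(m, 0) - 1, c2 = children(m, 1) - 1;
        for (int j = 0; j < 2; ++j) {
          uword c = j == 0 ? c1 : c2, sib = j == 0 ? c2 : c1;
          mat o = P.slice(c).t() * (out.slice(m) % msg.slice(sib));
          o.each_row() /= sum(o, 0);
          out.slice(c) = o;
        }
      }
      // root-state expectations
      mat rpost = inside.slice(root).each_col() % pi;
      rpost.each_row() /= sum(rpost, 0);
      n_root.row(k) = (rpost * gw).t();

      mat dwell(n_node, s, fill::zeros);
      cube counts(s, s, n_node, fill::zeros);
      mat tU = U.t(), tUinv = Uinv.t();
      for (uword m = 0; m < n_node - 1; ++m) {
        uword p = parent[m] - 1;
        vec norm = sum(out.slice(p) % msg.slice(m), 0).t();
        vec w = gw / norm;
        mat X = tU * out.slice(p);       // s x L
        mat Y = Uinv * inside.slice(m);  // s x L
        X.each_row() %= w.t();
        mat J = (X * Y.t()) % exp_integral(values, brlen[m]);
        mat M = tUinv * J * tU;
        vec dw = M.diag();
        dw.transform([](double x) { return x < 0 ? 0.0 : x; });
        dwell.row(m) = dw.t();
        mat cnt = R % M;
        cnt.diag().zeros();
        cnt.transform([](double x) { return x < 0 ? 0.0 : x; });
        counts.slice(m) = cnt;
      }
      statsOut[k] = Rcpp::List::create(
        Rcpp::Named("dwell") = dwell,
        Rcpp::Named("counts") = counts,
        Rcpp::Named("T") = sum(dwell, 0).t(),
        Rcpp::Named("N") = mat(sum(counts, 2)),
        Rcpp::Named("gamma_total") = accu(gw));
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("gamma") = gamma,
    Rcpp::Named("loglik") = loglik,
    Rcpp::Named("family_loglik") = family_loglik,
    Rcpp::Named("ll") = ll,
    Rcpp::Named("stats") = statsOut,
    Rcpp::Named("n_root") = n_root);
}
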