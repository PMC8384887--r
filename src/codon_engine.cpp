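// GY94-style codon substitution engine: Q construction, transition
// probabilities via eigendecomposition of the pi-symmetrized reversible
// form (scaling-and-squaring fallback), and Felsenstein pruning over a
// mixture of site classes with branch-group-specific omega.
//
// Conventions shared with the R side:
//  - codon states are 1-based indices into the sense-codon set (0 = missing),
//  - `pairtype` is an n x n integer matrix: 0 = inaccessible (0 or >1 nt
//    changes), 1 = synonymous transversion, 2 = synonymous transition,
//    3 = nonsynonymous transversion, 4 = nonsynonymous transition,
//  - `edge` is an ape-style postorder edge matrix (parent, child),
//  - `omegas` is C x G (site class x branch group), `props` length C.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_q(const arma::imat& pairtype, const arma::vec& pi,
                         double kappa, double omega, double* rate) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double r = 0.0;
      switch (pairtype(i, j)) {
        case 1: r = pi(j); break;
        case 2: r = kappa * pi(j); break;
        case 3: r = omega * pi(j); break;
        case 4: r = kappa * omega * pi(j); break;
        default: r = 0.0;
      }
      Q(i, j) = r;
      rowsum += r;
    }
    Q(i, i) = -rowsum;
  }
  if (rate) *rate = -arma::dot(pi, Q.diag());
  return Q;
}

// Spectral decomposition of a reversible Q: Q = D^{-1/2} U L U' D^{1/2}
struct QDecomp {
  arma::vec eval;
  arma::mat evec;   // of the symmetrized form
  arma::vec sqpi;
  bool ok;
  arma::mat Q;      // kept for the expmat fallback
};

static QDecomp decompose_q(const arma::mat& Q, const arma::vec& pi) {
  QDecomp d;
  d.sqpi = arma::sqrt(pi);
  arma::mat S = Q;
  S.each_col() %= d.sqpi;          // row i scaled by sqrt(pi_i)
  S.each_row() /= d.sqpi.t();      // col j scaled by 1/sqrt(pi_j)
  S = 0.5 * (S + S.t());
  d.ok = arma::eig_sym(d.eval, d.evec, S);
  d.Q = Q;
  return d;
}

static arma::mat pmat_from_decomp(const QDecomp& d, double t) {
  if (!d.ok) return arma::expmat(d.Q * t);
  arma::mat P = d.evec * arma::diagmat(arma::exp(d.eval * t)) * d.evec.t();
  P.each_col() /= d.sqpi;
  P.each_row() %= d.sqpi.t();
  P.elem(arma::find(P < 0)).zeros();
  return P;
}

// [[Rcpp::export(name = ".codon_build_q_cpp")]]
List codon_build_q_cpp(const arma::imat& pairtype, const arma::vec& pi,
                       double kappa, double omega) {
  double rate = 0.0;
  arma::mat Q = build_q(pairtype, pi, kappa, omega, &rate);
  return List::create(Named("Q") = Q, Named("rate") = rate);
}

// [[Rcpp::export(name = ".codon_pmat_cpp")]]
arma::mat codon_pmat_cpp(const arma::mat& Q, const arma::vec& pi, double t) {
  QDecomp d = decompose_q(Q, pi);
  return pmat_from_decomp(d, t);
}

// Per-pattern log-likelihoods under the site-class mixture.
// [[Rcpp::export(name = ".codon_loglik_cpp")]]
List codon_loglik_cpp(const arma::imat& tips, const arma::vec& weights,
                      const arma::imat& edge, const arma::vec& elen,
                      const arma::ivec& egroup, const arma::imat& pairtype,
                      const arma::vec& pi, double kappa,
                      const arma::mat& omegas, const arma::vec& props,
                      double scale_factor) {
  const int ntip = tips.n_rows;
  const int npat = tips.n_cols;
  const int nedge = edge.n_rows;
  const int nstate = pi.n_elem;
  const int nclass = omegas.n_rows;
  const int ngroup = omegas.n_cols;
  const int nnode = arma::max(arma::max(edge));

  // Build and decompose every distinct (class, group) generator once.
  std::vector<QDecomp> decomp(nclass * ngroup);
  std::vector<double> rate(nclass * ngroup);
  for (int c = 0; c < nclass; ++c)
    for (int g = 0; g < ngroup; ++g) {
      double r = 0.0;
      arma::mat Q = build_q(pairtype, pi, kappa, omegas(c, g), &r);
      rate[c * ngroup + g] = r;
      decomp[c * ngroup + g] = decompose_q(Q, pi);
    }

  // One common scale so a unit branch length is one expected substitution
  // per codon site, averaged over classes on the background (first) group.
  double f = scale_factor;
  if (f <= 0.0) {
    f = 0.0;
    for (int c = 0; c < nclass; ++c) f += props(c) * rate[c * ngroup];
  }
  if (f <= 0.0) stop("degenerate rate scale (all rates zero)");

  arma::mat sitelog(nclass, npat, arma::fill::zeros);

  for (int c = 0; c < nclass; ++c) {
    std::vector<arma::mat> partial(nnode + 1);
    arma::mat logscale(nnode + 1, npat, arma::fill::zeros);
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0), ch = edge(e, 1);
      if (partial[p].n_elem == 0)
        partial[p] = arma::mat(nstate, npat, arma::fill::ones);
      const int g = egroup(e) - 1;
      const QDecomp& d = decomp[c * ngroup + g];
      arma::mat P = pmat_from_decomp(d, elen(e) / f);
      if (ch <= ntip) {
        // tip child: columns of P (or ones for missing data)
        arma::mat& par = partial[p];
        for (int k = 0; k < npat; ++k) {
          const int s = tips(ch - 1, k);
          if (s > 0) par.col(k) %= P.col(s - 1);
        }
      } else {
        // rescale the completed child partial, then propagate
        arma::rowvec m = arma::max(partial[ch], 0);
        for (int k = 0; k < npat; ++k) {
          if (m(k) > 0 && m(k) < 1e-120) {
            partial[ch].col(k) /= m(k);
            logscale(ch, k) += std::log(m(k));
          }
        }
        partial[p] %= P * partial[ch];
        logscale.row(p) += logscale.row(ch);
        partial[ch].reset();
      }
    }
    const int root = edge(nedge - 1, 0);
    arma::rowvec rootL = pi.t() * partial[root];
    for (int k = 0; k < npat; ++k)
      sitelog(c, k) = (rootL(k) > 0 ? std::log(rootL(k)) : -1e300) +
                      logscale(root, k);
  }

  // log-sum-exp over classes with mixture weights
  arma::vec sitelnl(npat);
  for (int k = 0; k < npat; ++k) {
    double mx = -1e300;
    for (int c = 0; c < nclass; ++c)
      mx = std::max(mx, sitelog(c, k));
    double s = 0.0;
    for (int c = 0; c < nclass; ++c)
      s += props(c) * std::exp(sitelog(c, k) - mx);
    sitelnl(k) = mx + std::log(s);
  }
  return List::create(Named("lnL") = arma::dot(weights, sitelnl),
                      Named("site_lnL") = sitelnl,
                      Named("scale") = f);
}
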