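// Codon substitution model machinery: rate matrix construction, transition
// probabilities and Felsenstein pruning for site-class (branch-site) models.
// The rate matrix is the Goldman-Yang style parameterization
//   q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]
// for codon pairs differing at one position, normalized by the neutral
// (omega = 1) mean rate so the scale does not depend on omega or on the
// site-class weights.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int NC = 61;

// unnormalized Q; type codes: 0 none, 1 syn tv, 2 syn ts, 3 nonsyn tv, 4 nonsyn ts
static mat raw_q(const vec& pi, const imat& type, double kappa, double omega) {
  mat Q(NC, NC, fill::zeros);
  for (int i = 0; i < NC; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < NC; ++j) {
      int t = type(i, j);
      if (t == 0) continue;
      double r = pi(j);
      if (t == 2 || t == 4) r *= kappa;
      if (t >= 3) r *= omega;
      Q(i, j) = r;
      rowsum += r;
    }
    Q(i, i) = -rowsum;
  }
  return Q;
}

static double neutral_rate(const vec& pi, const imat& type, double kappa) {
  mat Q1 = raw_q(pi, type, kappa, 1.0);
  return -dot(pi, Q1.diag());
}

struct EigQ {
  vec eval;
  mat evec;      // of the symmetrized matrix
  vec sqp, isqp; // sqrt(pi), 1/sqrt(pi)
};

static EigQ eig_q(const vec& pi, const imat& type, double kappa, double omega,
                  double scale) {
  mat Q = raw_q(pi, type, kappa, omega) / scale;
  EigQ e;
  e.sqp = sqrt(pi);
  e.isqp = 1.0 / e.sqp;
  mat B = diagmat(e.sqp) * Q * diagmat(e.isqp);
  B = 0.5 * (B + B.t());   // symmetrize numerical noise
  eig_sym(e.eval, e.evec, B);
  return e;
}

static mat pmat_from_eig(const EigQ& e, double t) {
  mat P = diagmat(e.isqp) * e.evec * diagmat(exp(e.eval * t)) * e.evec.t() *
          diagmat(e.sqp);
  P.clamp(0.0, datum::inf);
  return P;
}

// [[Rcpp::export]]
arma::mat codon_rate_matrix_cpp(const arma::vec& pi, const arma::imat& type,
                                double kappa, double omega) {
  return raw_q(pi, type, kappa, omega) / neutral_rate(pi, type, kappa);
}

// [[Rcpp::export]]
arma::mat codon_pmat_cpp(const arma::vec& pi, const arma::imat& type,
                         double kappa, double omega, double t) {
  double scale = neutral_rate(pi, type, kappa);
  return pmat_from_eig(eig_q(pi, type, kappa, omega, scale), t);
}

// Per-class, per-site log-likelihoods for a site-class codon model.
//
// edge: nedge x 2 (parent, child), 1-based node ids, postorder (every edge
//   below a node precedes the edge where that node is the child). Tree is
//   rooted at `root`; when fg_edge > 0 the foreground edge must be incident
//   to the root (root is the parent endpoint), which the R caller arranges.
// tipstate: ntip x npat, values 1..61, 0 = missing (partial likelihood 1).
// bg_omega/fg_omega: one entry per site class.
//
// [[Rcpp::export]]
arma::mat class_site_loglik_cpp(const arma::imat& edge, const arma::vec& elen,
                                int fg_edge, const arma::imat& tipstate,
                                int nnode, int root, const arma::vec& pi,
                                const arma::imat& type, double kappa,
                                const arma::vec& bg_omega,
                                const arma::vec& fg_omega) {
  const int nedge = edge.n_rows;
  const int ntip = tipstate.n_rows;
  const int npat = tipstate.n_cols;
  const int K = bg_omega.n_elem;
  const double scale = neutral_rate(pi, type, kappa);

  std::map<double, EigQ> eigs;
  for (int k = 0; k < K; ++k) {
    if (!eigs.count(bg_omega(k)))
      eigs[bg_omega(k)] = eig_q(pi, type, kappa, bg_omega(k), scale);
    if (!eigs.count(fg_omega(k)))
      eigs[fg_omega(k)] = eig_q(pi, type, kappa, fg_omega(k), scale);
  }

  int fg_child = fg_edge > 0 ? edge(fg_edge - 1, 1) : -1;
  if (fg_edge > 0 && edge(fg_edge - 1, 0) != root)
    Rcpp::stop("foreground edge must be incident to the root");

  mat out(K, npat);
  std::map<double, int> done_bg; // bg omega -> index into computed results
  std::vector<std::vector<int>> root_children;
  std::vector<std::vector<mat>> root_contrib; // per bg pass, per root child
  std::vector<mat> fg_partial;                // L at fg child, per bg pass
  std::vector<double> fg_len;
  std::vector<rowvec> scales;

  for (int k = 0; k < K; ++k) {
    double bg = bg_omega(k);
    int pass;
    if (done_bg.count(bg)) {
      pass = done_bg[bg];
    } else {
      pass = root_contrib.size();
      done_bg[bg] = pass;
      const EigQ& e = eigs[bg];
      std::vector<mat> L(nnode + 1);
      for (int n = 1; n <= ntip; ++n) {
        L[n] = mat(NC, npat, fill::zeros);
        for (int s = 0; s < npat; ++s) {
          int st = tipstate(n - 1, s);
          if (st == 0) L[n].col(s).ones();
          else L[n](st - 1, s) = 1.0;
        }
      }
      for (int n = ntip + 1; n <= nnode; ++n) L[n] = mat(NC, npat, fill::ones);
      rowvec logscale(npat, fill::zeros);
      std::vector<int> rchild;
      std::vector<mat> rcontrib;
      double flen = 0.0;
      for (int eidx = 0; eidx < nedge; ++eidx) {
        int p = edge(eidx, 0), c = edge(eidx, 1);
        if (c > ntip) { // internal child is complete: rescale
          rowvec m = max(L[c], 0);
          m.transform([](double v) { return v > 0 ? v : 1.0; });
          L[c].each_row() /= m;
          logscale += log(m);
        }
        mat P = pmat_from_eig(e, elen(eidx));
        mat contrib = P.t() * L[c];
        if (p == root) {
          rchild.push_back(c);
          rcontrib.push_back(contrib);
          if (eidx == fg_edge - 1) flen = elen(eidx);
        } else {
          L[p] %= contrib;
        }
      }
      root_children.push_back(rchild);
      root_contrib.push_back(rcontrib);
      fg_partial.push_back(fg_child > 0 ? L[fg_child] : mat());
      fg_len.push_back(flen);
      scales.push_back(logscale);
    }

    // combine root contributions; swap in the foreground edge for this class
    const std::vector<int>& rchild = root_children[pass];
    const std::vector<mat>& rcontrib = root_contrib[pass];
    mat rootprod(NC, npat, fill::ones);
    for (size_t ci = 0; ci < rchild.size(); ++ci) {
      if (fg_child > 0 && rchild[ci] == fg_child && fg_omega(k) != bg) {
        mat Pf = pmat_from_eig(eigs[fg_omega(k)], fg_len[pass]);
        rootprod %= Pf.t() * fg_partial[pass];
      } else if (fg_child > 0 && rchild[ci] == fg_child) {
        rootprod %= rcontrib[ci]; // fg omega equals bg omega: reuse
      } else {
        rootprod %= rcontrib[ci];
      }
    }
    rowvec sitelik = pi.t() * rootprod;
    sitelik.transform([](double v) { return v > 0 ? v : 1e-300; });
    out.row(k) = log(sitelik) + scales[pass];
  }
  return out;
}
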