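// Felsenstein pruning for codon site-class mixture models.
//
// The tree arrives as a postorder edge list (children complete before their
// parent's edge is used). Each site class assigns one rate system (an
// eigendecomposition of a scaled GY94 generator) to background branches and
// one to the foreground branch. Per-class transition matrices are cached by
// (rate system, edge) so classes sharing a system on a branch do not repeat
// the matrix exponential. Underflow is handled by per-node rescaling with log
// accumulation, so the returned log-likelihoods are exact regardless of the
// scaling path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_bs_lnl(const arma::imat& edges,      // nedge x 2 (parent, child), 1-based
                int nnode,                    // total nodes (tips + internals)
                int ntip,
                const List& tip_partials,     // per tip: s x npat matrix
                const List& eigA,             // per rate system: s x s
                const List& eigB,
                const List& eigLambda,        // per rate system: s
                const arma::vec& brlen,       // per edge
                const arma::ivec& class_bg,   // per class: rate system, 1-based
                const arma::ivec& class_fg,
                int fg_edge,                  // 1-based edge index, 0 = none
                const arma::vec& class_weights,
                const arma::vec& pat_weights,
                const arma::vec& pi,
                bool return_site_matrix) {
  const int nedge = edges.n_rows;
  const int nclass = class_bg.n_elem;
  const int s = pi.n_elem;
  const int npat = pat_weights.n_elem;
  const int nsys = eigA.size();

  std::vector<arma::mat> A(nsys), B(nsys);
  std::vector<arma::vec> lam(nsys);
  for (int k = 0; k < nsys; ++k) {
    A[k] = as<arma::mat>(eigA[k]);
    B[k] = as<arma::mat>(eigB[k]);
    lam[k] = as<arma::vec>(eigLambda[k]);
  }

  // transition matrix cache keyed by rate system x edge
  std::vector<arma::mat> pcache((size_t)nsys * nedge);
  std::vector<bool> phave((size_t)nsys * nedge, false);
  auto getP = [&](int sys, int e) -> const arma::mat& {
    size_t key = (size_t)sys * nedge + e;
    if (!phave[key]) {
      arma::mat expd = B[sys];
      expd.each_col() %= arma::exp(lam[sys] * brlen[e]);
      pcache[key] = A[sys] * expd;
      pcache[key].transform([](double v) { return v < 0.0 ? 0.0 : v; });
      phave[key] = true;
    }
    return pcache[key];
  };

  arma::mat site_log(nclass, npat);

  arma::mat partial(s, npat);
  std::vector<arma::mat> node_part(nnode);
  std::vector<bool> started(nnode);
  arma::rowvec scalelog(npat);

  for (int k = 0; k < nclass; ++k) {
    std::fill(started.begin(), started.end(), false);
    scalelog.zeros();
    for (int e = 0; e < nedge; ++e) {
      const int parent = edges(e, 0) - 1;
      const int child = edges(e, 1) - 1;
      const int sys = (e + 1 == fg_edge) ? class_fg[k] - 1 : class_bg[k] - 1;
      const arma::mat& P = getP(sys, e);
      const arma::mat& cpart = (child < ntip)
        ? as<arma::mat>(tip_partials[child])
        : node_part[child];
      partial = P * cpart;
      if (!started[parent]) {
        node_part[parent] = partial;
        started[parent] = true;
      } else {
        node_part[parent] %= partial;
        // rescale to avoid underflow as factors accumulate
        arma::rowvec mx = arma::max(node_part[parent], 0);
        for (int j = 0; j < npat; ++j) {
          if (mx[j] > 0 && mx[j] < 1e-100) {
            node_part[parent].col(j) /= mx[j];
            scalelog[j] += std::log(mx[j]);
          }
        }
      }
    }
    const int root = edges(nedge - 1, 0) - 1;
    arma::rowvec lik = pi.t() * node_part[root];
    for (int j = 0; j < npat; ++j) {
      site_log(k, j) = (lik[j] > 0 ? std::log(lik[j]) : R_NegInf) + scalelog[j];
    }
  }

  // mix classes in log space
  double lnl = 0.0;
  arma::vec lw = arma::log(class_weights);
  for (int j = 0; j < npat; ++j) {
    double m = R_NegInf;
    for (int k = 0; k < nclass; ++k) {
      double v = lw[k] + site_log(k, j);
      if (v > m) m = v;
    }
    double acc = 0.0;
    if (m > R_NegInf) {
      for (int k = 0; k < nclass; ++k) acc += std::exp(lw[k] + site_log(k, j) - m);
      lnl += pat_weights[j] * (m + std::log(acc));
    } else {
      lnl = R_NegInf;
      break;
    }
  }

  if (return_site_matrix) {
    return List::create(_["lnl"] = lnl, _["site_log"] = site_log);
  }
  return List::create(_["lnl"] = lnl);
}
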