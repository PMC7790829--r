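#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for Brownian motion on a rooted tree with a fixed
// root state. Edges must be in ape "postorder" order (children before
// parents). Returns c(loglik, mu_root, v_root, logf) where
//   loglik = logf + dnorm(root_state; mu_root, sqrt(sigma2 * v_root))
// so callers can re-evaluate the likelihood at any root state from the
// same pass. `rates` are per-edge multiplicative scalars on branch length
// (background 1); `x` holds tip values in tip-index order, already
// mean-adjusted for any directional component.
// [[Rcpp::export]]
NumericVector bm_prune_cpp(IntegerMatrix edge, NumericVector edge_len,
                           NumericVector rates, int n_tip,
                           NumericVector x, double sigma2,
                           double root_state) {
  const int n_edge = edge.nrow();
  const int n_node = n_tip + n_edge + 1;  // upper bound on node ids
  std::vector<double> mu(n_node, 0.0), v(n_node, 0.0);
  std::vector<int> seen(n_node, 0);
  double logf = 0.0;

  for (int i = 0; i < n_tip; ++i) { mu[i] = x[i]; v[i] = 0.0; seen[i] = 1; }

  for (int e = 0; e < n_edge; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    if (!seen[chi]) stop("edge order is not postorder");
    const double mc = mu[chi];
    const double vc = v[chi] + edge_len[e] * rates[e];
    if (!seen[par]) {
      mu[par] = mc; v[par] = vc; seen[par] = 1;
    } else {
      const double v1 = v[par], v2 = vc, m1 = mu[par], m2 = mc;
      const double vs = v1 + v2;
      logf += R::dnorm(m1 - m2, 0.0, std::sqrt(sigma2 * vs), 1);
      mu[par] = (m1 * v2 + m2 * v1) / vs;
      v[par]  = v1 * v2 / vs;
    }
  }

  const int root = edge(n_edge - 1, 0) - 1;
  double ll = logf +
    R::dnorm(root_state, mu[root], std::sqrt(sigma2 * v[root]), 1);
  return NumericVector::create(ll, mu[root], v[root], logf);
}
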