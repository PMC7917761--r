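// Greedy regression-tree fitting on two-pixel difference features.
//
// The tree is a complete binary heap of depth F: internal nodes 1..2^F-1,
// leaves 2^F..2^(F+1)-1. Each internal node stores (u, v, theta) and routes a
// sample left when feat[u] - feat[v] <= theta. Unsplit (degenerate) nodes are
// pass-through: a zero-effect split with theta = +Inf sending everything left.
// Leaves hold the mean residual of the samples reaching them (the caller
// applies shrinkage); empty leaves hold zeros.
//
// Residuals are passed transposed (D x n) so a sample's residual is a
// contiguous column.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Best {
  double score = -1.0;
  int u = -1, v = -1;
  double theta = 0.0;
  bool found = false;
};

// Score a fixed (u, v, theta): between-child sum-of-squares of residuals.
inline double score_split(const arma::mat& residT,
                          const std::vector<int>& idx,
                          const std::vector<double>& f, double theta,
                          const arma::vec& sum_tot, arma::vec& sum_left,
                          int min_leaf, bool& ok) {
  const size_t n = idx.size();
  sum_left.zeros();
  size_t n_left = 0;
  for (size_t i = 0; i < n; ++i) {
    if (f[i] <= theta) {
      sum_left += residT.unsafe_col(idx[i]);
      ++n_left;
    }
  }
  const size_t n_right = n - n_left;
  if (min_leaf > 1 &&
      (n_left < (size_t)min_leaf || n_right < (size_t)min_leaf)) {
    ok = false;
    return -1.0;
  }
  ok = true;
  double s = 0.0;
  const double ll = arma::dot(sum_left, sum_left);
  if (n_left > 0) s += ll / (double)n_left;
  if (n_right > 0) {
    // ||S_R||^2 = ||S_tot||^2 + ||S_L||^2 - 2 <S_tot, S_L>
    const double rr = arma::dot(sum_tot, sum_tot) + ll -
      2.0 * arma::dot(sum_tot, sum_left);
    s += rr / (double)n_right;
  }
  return s;
}

} // namespace

// [[Rcpp::export(name = ".fitTreeCpp")]]
List fit_tree_cpp(const arma::mat& feat,     // n x P intensities
                  const arma::mat& residT,   // D x n residuals (transposed)
                  int depth,
                  IntegerMatrix cand_u,      // n_internal x C, 1-based
                  IntegerMatrix cand_v,
                  NumericMatrix cand_r,      // uniforms in [0,1) for theta
                  bool exhaustive,
                  int min_leaf) {
  const int n = feat.n_rows;
  const int P = feat.n_cols;
  const int D = residT.n_rows;
  if (depth < 1) stop("config error: depth must be >= 1");
  if (n < 1) stop("value error: no samples");

  const int n_internal = (1 << depth) - 1;
  const int n_leaves = 1 << depth;

  IntegerVector out_u(n_internal), out_v(n_internal);
  NumericVector out_theta(n_internal);
  // Sample lists per heap node (1-based heap in 0-based vector of size 2^(F+1)).
  std::vector<std::vector<int> > node_idx(2 * n_leaves);
  node_idx[1].resize(n);
  for (int i = 0; i < n; ++i) node_idx[1][i] = i;

  std::vector<double> fbuf(n);
  arma::vec sum_left(D), sum_best(D);

  for (int node = 1; node <= n_internal; ++node) {
    const std::vector<int>& idx = node_idx[node];
    Best best;

    if (idx.size() >= 2) {
      arma::vec sum_tot(D, arma::fill::zeros);
      for (size_t i = 0; i < idx.size(); ++i)
        sum_tot += residT.unsafe_col(idx[i]);

      if (exhaustive) {
        // All unordered probe pairs x all midpoints between consecutive
        // distinct observed feature values at this node.
        for (int u = 0; u < P; ++u) {
          const double* cu = feat.colptr(u);
          for (int v = u + 1; v < P; ++v) {
            const double* cv = feat.colptr(v);
            for (size_t i = 0; i < idx.size(); ++i)
              fbuf[i] = cu[idx[i]] - cv[idx[i]];
            std::vector<double> vals(fbuf.begin(), fbuf.begin() + idx.size());
            std::sort(vals.begin(), vals.end());
            vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
            for (size_t k = 0; k + 1 < vals.size(); ++k) {
              const double theta = 0.5 * (vals[k] + vals[k + 1]);
              bool ok;
              double s = score_split(residT, idx, fbuf, theta, sum_tot,
                                     sum_left, min_leaf, ok);
              if (ok && (!best.found || s > best.score)) {
                best.score = s; best.u = u; best.v = v; best.theta = theta;
                best.found = true;
              }
            }
          }
        }
      } else {
        const int C = cand_u.ncol();
        const int row = node - 1;
        for (int c = 0; c < C; ++c) {
          const int u = cand_u(row, c) - 1;
          const int v = cand_v(row, c) - 1;
          if (u < 0 || u >= P || v < 0 || v >= P || u == v)
            stop("invalid candidate probe pair");
          const double* cu = feat.colptr(u);
          const double* cv = feat.colptr(v);
          double fmin = R_PosInf, fmax = R_NegInf;
          for (size_t i = 0; i < idx.size(); ++i) {
            const double f = cu[idx[i]] - cv[idx[i]];
            fbuf[i] = f;
            if (f < fmin) fmin = f;
            if (f > fmax) fmax = f;
          }
          // theta drawn uniformly between the observed min and max.
          const double theta = fmin + cand_r(row, c) * (fmax - fmin);
          bool ok;
          double s = score_split(residT, idx, fbuf, theta, sum_tot, sum_left,
                                 min_leaf, ok);
          // strict > : ties broken by first-seen candidate order
          if (ok && (!best.found || s > best.score)) {
            best.score = s; best.u = u; best.v = v; best.theta = theta;
            best.found = true;
          }
        }
      }
    }

    if (best.found) {
      out_u[node - 1] = best.u + 1;
      out_v[node - 1] = best.v + 1;
      out_theta[node - 1] = best.theta;
      const double* cu = feat.colptr(best.u);
      const double* cv = feat.colptr(best.v);
      std::vector<int>& L = node_idx[2 * node];
      std::vector<int>& Rn = node_idx[2 * node + 1];
      for (size_t i = 0; i < idx.size(); ++i) {
        const double f = cu[idx[i]] - cv[idx[i]];
        if (f <= best.theta) L.push_back(idx[i]); else Rn.push_back(idx[i]);
      }
    } else {
      // pass-through: zero-effect split, everything left
      out_u[node - 1] = 1;
      out_v[node - 1] = (P >= 2) ? 2 : 1;
      out_theta[node - 1] = R_PosInf;
      node_idx[2 * node] = idx;
    }
  }

  NumericMatrix leaves(n_leaves, D);
  IntegerVector leaf_index(n);
  for (int l = 0; l < n_leaves; ++l) {
    const std::vector<int>& idx = node_idx[n_leaves + l];
    if (idx.empty()) continue;
    arma::vec mu(D, arma::fill::zeros);
    for (size_t i = 0; i < idx.size(); ++i) {
      mu += residT.unsafe_col(idx[i]);
      leaf_index[idx[i]] = l + 1;
    }
    mu /= (double)idx.size();
    for (int d = 0; d < D; ++d) leaves(l, d) = mu[d];
  }

  return List::create(_["u"] = out_u, _["v"] = out_v, _["theta"] = out_theta,
                      _["leaves"] = leaves, _["leafIndex"] = leaf_index);
}
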