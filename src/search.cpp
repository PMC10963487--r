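// Fast inner loops for constraint-based search: level-wise PC skeleton
// deletion driven by Fisher-z tests on a cached correlation matrix, and
// subset searches for separating sets (used by the FCI possible-d-sep
// stage). Orientation rules live in R; only the test-heavy loops are
// compiled.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// partial correlation of x,y given S via inversion of the correlation
// submatrix; indices are 0-based
static double pcor(const arma::mat& C, int x, int y,
                   const std::vector<int>& S) {
  const int k = (int)S.size();
  if (k == 0) return C(x, y);
  if (k == 1) {
    const int z = S[0];
    const double num = C(x, y) - C(x, z) * C(y, z);
    const double den = std::sqrt((1.0 - C(x, z) * C(x, z)) *
                                 (1.0 - C(y, z) * C(y, z)));
    if (den <= 0) stop("collinearity: degenerate conditioning on variable %d", z + 1);
    return num / den;
  }
  if (k <= 8) {
    // Schur complement with a stack-allocated Gaussian solve:
    // r = (C_xy - C_xS W_y) / sqrt((C_xx - C_xS W_x)(C_yy - C_yS W_y))
    // where W_* solves C_SS W = C_S*
    double Ms[64], rhs[16];
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < k; ++j) Ms[i * k + j] = C(S[i], S[j]);
      rhs[i * 2]     = C(S[i], x);
      rhs[i * 2 + 1] = C(S[i], y);
    }
    for (int col = 0; col < k; ++col) {               // partial pivoting
      int piv = col;
      for (int i = col + 1; i < k; ++i)
        if (std::abs(Ms[i * k + col]) > std::abs(Ms[piv * k + col])) piv = i;
      if (std::abs(Ms[piv * k + col]) < 1e-12)
        stop("collinearity: singular correlation submatrix in CI test");
      if (piv != col) {
        for (int j = 0; j < k; ++j) std::swap(Ms[piv * k + j], Ms[col * k + j]);
        std::swap(rhs[piv * 2], rhs[col * 2]);
        std::swap(rhs[piv * 2 + 1], rhs[col * 2 + 1]);
      }
      const double d = Ms[col * k + col];
      for (int i = 0; i < k; ++i) {
        if (i == col) continue;
        const double f = Ms[i * k + col] / d;
        if (f == 0.0) continue;
        for (int j = col; j < k; ++j) Ms[i * k + j] -= f * Ms[col * k + j];
        rhs[i * 2] -= f * rhs[col * 2];
        rhs[i * 2 + 1] -= f * rhs[col * 2 + 1];
      }
    }
    double cxy = C(x, y), cxx = 1.0, cyy = 1.0;
    for (int i = 0; i < k; ++i) {
      const double wx = rhs[i * 2] / Ms[i * k + i];
      const double wy = rhs[i * 2 + 1] / Ms[i * k + i];
      cxy -= C(S[i], x) * wy;
      cxx -= C(S[i], x) * wx;
      cyy -= C(S[i], y) * wy;
    }
    const double den = cxx * cyy;
    if (den <= 0)
      stop("collinearity: singular correlation submatrix in CI test");
    double r = cxy / std::sqrt(den);
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
    return r;
  }
  arma::uvec idx(k + 2);
  idx(0) = x; idx(1) = y;
  for (int i = 0; i < k; ++i) idx(i + 2) = S[i];
  arma::mat sub = C.submat(idx, idx);
  arma::mat Om;
  const bool ok = arma::inv(Om, sub);
  if (!ok || Om(0, 0) <= 0 || Om(1, 1) <= 0)
    stop("collinearity: singular correlation submatrix in CI test");
  double r = -Om(0, 1) / std::sqrt(Om(0, 0) * Om(1, 1));
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// two-sided Fisher-z p-value
static double fisherz_p(double r, double n, int sizeS) {
  if (std::abs(r) >= 1.0) return 0.0;
  const double z = std::sqrt(n - sizeS - 3.0) * std::atanh(r);
  return 2.0 * R::pnorm(-std::abs(z), 0.0, 1.0, 1, 0);
}

// advance a size-k combination over 0..(m-1); returns false when done
static bool next_comb(std::vector<int>& comb, int m) {
  int k = (int)comb.size();
  int i = k - 1;
  while (i >= 0 && comb[i] == m - k + i) --i;
  if (i < 0) return false;
  ++comb[i];
  for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
  return true;
}

// [[Rcpp::export(name = ".pc_skeleton_cpp")]]
List pc_skeleton_cpp(const arma::mat& C, double n, double alpha,
                     IntegerVector order, int variant,
                     LogicalMatrix fixed_gaps, int max_cond) {
  // variant: 0 = original (adjacency mutates immediately),
  //          1 = stable (adjacencies frozen per depth),
  //          2 = parallel (stable with batched per-depth application)
  const int V = C.n_rows;
  std::vector<std::vector<bool>> adj(V, std::vector<bool>(V, true));
  for (int i = 0; i < V; ++i) adj[i][i] = false;
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < V; ++j)
      if (fixed_gaps(i, j)) { adj[i][j] = false; adj[j][i] = false; }

  List sepsets(V * V);
  long n_tests = 0;

  // rank of each variable in the visiting order; order is a permutation
  // of 0..V-1 giving the visit sequence
  std::vector<int> rank(V);
  for (int i = 0; i < V; ++i) rank[order[i]] = i;

  int ell = 0;
  const int ell_max = (max_cond < 0) ? V - 2 : max_cond;
  while (ell <= ell_max) {
    // does any ordered adjacent pair still admit a size-ell subset?
    bool any = false;
    for (int x = 0; x < V && !any; ++x) {
      int deg = 0;
      for (int j = 0; j < V; ++j) if (adj[x][j]) ++deg;
      if (deg - 1 >= ell) {
        for (int j = 0; j < V; ++j) if (adj[x][j]) { any = true; break; }
      }
    }
    if (!any) break;

    std::vector<std::vector<bool>> frozen = adj;  // per-depth snapshot
    const std::vector<std::vector<bool>>& base =
      (variant == 0) ? adj : frozen;

    struct Removal { int x, y; std::vector<int> S; };
    std::vector<Removal> batch;

    for (int oi = 0; oi < V; ++oi) {
      const int x = order[oi];
      for (int oj = 0; oj < V; ++oj) {
        const int y = order[oj];
        if (x == y) continue;
        if (variant == 2) { if (!frozen[x][y]) continue; }
        else if (!adj[x][y]) continue;

        // neighbors of x other than y, in visit order ("frozen
        // adjacency list"); subsets enumerated lexicographically
        std::vector<int> nbrs;
        for (int r = 0; r < V; ++r) {
          const int v = order[r];
          if (v != y && base[x][v]) nbrs.push_back(v);
        }
        const int m = (int)nbrs.size();
        if (m < ell) continue;

        std::vector<int> comb(ell);
        for (int i = 0; i < ell; ++i) comb[i] = i;
        bool removed = false;
        do {
          std::vector<int> S(ell);
          for (int i = 0; i < ell; ++i) S[i] = nbrs[comb[i]];
          const double r = pcor(C, x, y, S);
          ++n_tests;
          if (fisherz_p(r, n, ell) > alpha) {
            if (variant == 2) {
              batch.push_back({x, y, S});
            } else {
              adj[x][y] = false; adj[y][x] = false;
              IntegerVector Sv(S.begin(), S.end());
              sepsets[x * V + y] = Sv + 1;  // 1-based for R
              sepsets[y * V + x] = Sv + 1;
            }
            removed = true;
            break;
          }
        } while (ell > 0 && next_comb(comb, m));
        if (ell == 0 && !removed) continue;
      }
    }

    if (variant == 2) {
      // apply in visit order, first decision wins (matches the
      // sequential stable sweep exactly)
      for (const auto& rm : batch) {
        if (!adj[rm.x][rm.y]) continue;
        adj[rm.x][rm.y] = false; adj[rm.y][rm.x] = false;
        IntegerVector Sv(rm.S.begin(), rm.S.end());
        sepsets[rm.x * V + rm.y] = Sv + 1;
        sepsets[rm.y * V + rm.x] = Sv + 1;
      }
    }
    ++ell;
  }

  LogicalMatrix A(V, V);
  for (int i = 0; i < V; ++i)
    for (int j = 0; j < V; ++j) A(i, j) = adj[i][j];
  return List::create(_["adj"] = A, _["sepsets"] = sepsets,
                      _["n_tests"] = (double)n_tests,
                      _["max_depth"] = ell - 1);
}

// search for a separating subset of `candidates` (1-based indices) for
// the pair x,y (1-based); subsets enumerated by size then
// lexicographically; returns the first separating set or NULL
// [[Rcpp::export(name = ".find_sepset_cpp")]]
SEXP find_sepset_cpp(const arma::mat& C, double n, double alpha,
                     int x, int y, IntegerVector candidates,
                     int min_size, int max_size) {
  const int m = candidates.size();
  const int x0 = x - 1, y0 = y - 1;
  const int top = (max_size < 0 || max_size > m) ? m : max_size;
  for (int k = min_size; k <= top; ++k) {
    if (n - k - 3 <= 0) break;
    std::vector<int> comb(k);
    for (int i = 0; i < k; ++i) comb[i] = i;
    bool more = true;
    while (more) {
      std::vector<int> S(k);
      for (int i = 0; i < k; ++i) S[i] = candidates[comb[i]] - 1;
      const double r = pcor(C, x0, y0, S);
      if (fisherz_p(r, n, k) > alpha) {
        IntegerVector out(k);
        for (int i = 0; i < k; ++i) out[i] = S[i] + 1;
        return out;
      }
      more = (k > 0) && next_comb(comb, m);
      if (k == 0) more = false;
    }
  }
  return R_NilValue;
}
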