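#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double eucl(double ax, double ay, double bx, double by) {
  const double dx = ax - bx, dy = ay - by;
  return std::sqrt(dx * dx + dy * dy);
}

// Unconstrained DTW cost (sum of local Euclidean costs along the optimal
// monotone path). Rolling two-row DP: O(n*m) time, O(m) memory, so full
// trajectories (thousands of samples) fit comfortably.
// [[Rcpp::export(name = ".dtw_cost_full")]]
double dtw_cost_full(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by) {
  const int n = ax.size(), m = bx.size();
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = inf;
    for (int j = 1; j <= m; ++j) {
      const double c = eucl(ax[i - 1], ay[i - 1], bx[j - 1], by[j - 1]);
      double best = prev[j];                       // insertion
      if (prev[j - 1] < best) best = prev[j - 1];  // match
      if (cur[j - 1] < best) best = cur[j - 1];    // deletion
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Window-constrained DTW with backtracked path. The window is a contiguous
// column band per row: row i (1-based) may use columns jmin[i-1]..jmax[i-1].
// Used both by the FastDTW refinement step (narrow band) and, with a full
// band, as the exact base case. Returns the cost and the optimal path as a
// 2-column (i, j) matrix in 1-based indices.
// [[Rcpp::export(name = ".dtw_cost_window")]]
List dtw_cost_window(NumericVector ax, NumericVector ay,
                     NumericVector bx, NumericVector by,
                     IntegerVector jmin, IntegerVector jmax) {
  const int n = ax.size(), m = bx.size();
  const double inf = std::numeric_limits<double>::infinity();

  // offsets into a flat store of window cells
  std::vector<int> off(n + 1, 0);
  int ncell = 0;
  for (int i = 0; i < n; ++i) {
    off[i] = ncell;
    ncell += jmax[i] - jmin[i] + 1;
  }
  off[n] = ncell;
  std::vector<double> D(ncell, inf);
  std::vector<signed char> bp(ncell, -1); // 0=diag, 1=up, 2=left

  auto idx = [&](int i, int j) -> int { // i,j 1-based; -1 if outside window
    if (i < 1 || i > n) return -1;
    if (j < jmin[i - 1] || j > jmax[i - 1]) return -1;
    return off[i - 1] + (j - jmin[i - 1]);
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = jmin[i - 1]; j <= jmax[i - 1]; ++j) {
      const double c = eucl(ax[i - 1], ay[i - 1], bx[j - 1], by[j - 1]);
      double best = inf;
      signed char move = -1;
      if (i == 1 && j == 1) {
        best = 0.0; move = -1;
      } else {
        int p = idx(i - 1, j - 1);
        if (p >= 0 && D[p] < best) { best = D[p]; move = 0; }
        p = idx(i - 1, j);
        if (p >= 0 && D[p] < best) { best = D[p]; move = 1; }
        p = idx(i, j - 1);
        if (p >= 0 && D[p] < best) { best = D[p]; move = 2; }
      }
      const int q = idx(i, j);
      if (std::isfinite(best)) {
        D[q] = c + best;
        bp[q] = move;
      }
    }
  }

  const int qend = idx(n, m);
  if (qend < 0 || !std::isfinite(D[qend]))
    stop("DTW window does not admit a monotone path from (1,1) to (n,m)");

  // backtrack
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (true) {
    pi.push_back(i); pj.push_back(j);
    const int q = idx(i, j);
    const signed char mv = bp[q];
    if (mv < 0) break;
    if (mv == 0) { --i; --j; }
    else if (mv == 1) { --i; }
    else { --j; }
  }
  const int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) { // reverse into forward order
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["cost"] = D[qend], _["path"] = path);
}
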