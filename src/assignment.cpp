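#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Jonker-Volgenant shortest augmenting path solver for the square linear
// assignment problem. Returns the optimal column for each row (1-based).
// Used for exact optimal transport between equal-size uniform point clouds:
// by Birkhoff's theorem the optimum of the transport LP with uniform
// marginals and n1 == n2 is attained at a permutation matrix.
// [[Rcpp::export]]
IntegerVector solve_assignment_cpp(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();

  // potentials and matching; 0-based internally, row -> col in 'match_row'
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, n);   // p[j] = row matched to column j (n = free)
  std::vector<int> way(n + 1, 0);

  for (int i = 0; i < n; ++i) {
    // augmenting path from row i
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    int j0 = n;                  // virtual free column
    p[n] = i;
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 0; j < n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0, j) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != n);
    // unwind
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0 != n);
  }

  IntegerVector match(n);
  for (int j = 0; j < n; ++j) match[p[j]] = j + 1;
  return match;
}
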