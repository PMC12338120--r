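#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Shortest-augmenting-path solver for the rectangular linear assignment
// problem.  Assigns every row of `cost` (nrow <= ncol) to a distinct column
// so that the total cost is minimal.  Dual potentials u, v maintain reduced
// costs; one Dijkstra-style search per row.  O(n^2 m) worst case, which is
// ample for eigenvalue lists of a few hundred entries.
//
// Returns 0-based column index assigned to each row.
// [[Rcpp::export]]
IntegerVector lap_solve_cpp(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr == 0) return IntegerVector(0);
  if (nr > nc) stop("cost matrix must have nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> u(nr, 0.0), v(nc, 0.0), spc(nc);
  std::vector<int> col4row(nr, -1), row4col(nc, -1), path(nc, -1);
  std::vector<char> SR(nr), SC(nc);

  for (int curRow = 0; curRow < nr; ++curRow) {
    double minVal = 0.0;
    int i = curRow, sink = -1;
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(spc.begin(), spc.end(), INF);

    while (sink == -1) {
      SR[i] = 1;
      double lowest = INF;
      int jlow = -1;
      for (int j = 0; j < nc; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < spc[j]) { spc[j] = r; path[j] = i; }
        if (spc[j] < lowest ||
            (spc[j] == lowest && row4col[j] == -1 && jlow >= 0 && row4col[jlow] != -1)) {
          lowest = spc[j];
          jlow = j;
        }
      }
      minVal = lowest;
      if (!std::isfinite(minVal)) stop("infeasible assignment problem");
      SC[jlow] = 1;
      if (row4col[jlow] == -1) sink = jlow; else i = row4col[jlow];
    }

    u[curRow] += minVal;
    for (int k = 0; k < nr; ++k)
      if (SR[k] && k != curRow) u[k] += minVal - spc[col4row[k]];
    for (int j = 0; j < nc; ++j)
      if (SC[j]) v[j] -= minVal - spc[j];

    int j = sink;
    for (;;) {
      int ii = path[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      if (ii == curRow) break;
      j = tmp;
    }
  }
  return IntegerVector(col4row.begin(), col4row.end());
}
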