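#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Square linear assignment problem, shortest-augmenting-path method with
// dual potentials (Jonker-Volgenant family, O(n^3)).  Costs must be finite;
// forbidden entries are encoded upstream as a large sentinel.  Rows are
// augmented in index order, which makes the returned optimum deterministic.
//
// Returns a 1-based column index for every row.
// [[Rcpp::export]]
IntegerVector lap_solve_cpp(NumericMatrix a) {
    const int n = a.nrow();
    if (a.ncol() != n) stop("cost matrix must be square");
    if (n == 0) return IntegerVector(0);

    const double INF = std::numeric_limits<double>::max() / 4.0;
    std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
    // p[j] = row matched to column j (1-based; 0 = free), p[0] = current row
    std::vector<int> p(n + 1, 0), way(n + 1, 0);

    for (int i = 1; i <= n; ++i) {
        p[0] = i;
        int j0 = 0;
        std::vector<double> minv(n + 1, INF);
        std::vector<char> used(n + 1, 0);
        do {
            used[j0] = 1;
            const int i0 = p[j0];
            int j1 = -1;
            double delta = INF;
            for (int j = 1; j <= n; ++j) {
                if (used[j]) continue;
                const double cur = a(i0 - 1, j - 1) - u[i0] - v[j];
                if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
                if (minv[j] < delta) { delta = minv[j]; j1 = j; }
            }
            if (j1 < 0) stop("assignment problem is infeasible");
            for (int j = 0; j <= n; ++j) {
                if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
                else          minv[j] -= delta;
            }
            j0 = j1;
        } while (p[j0] != 0);
        do { const int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
    }

    IntegerVector ans(n);
    for (int j = 1; j <= n; ++j) if (p[j] > 0) ans[p[j] - 1] = j;
    return ans;
}
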