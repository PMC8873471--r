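// Evaluation kernels: 26-connectivity 3D connected-component labeling
// (iterative BFS) and a Jonker-Volgenant-style shortest-augmenting-path
// solver for the linear assignment problem (square cost matrix).
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector label_components_cpp(IntegerVector mask) {
  IntegerVector d = as<IntegerVector>(mask.attr("dim"));
  const int X = d[0], Y = d[1], Z = d[2];
  const R_xlen_t n = static_cast<R_xlen_t>(X) * Y * Z;
  IntegerVector labels(n);
  labels.attr("dim") = d;
  const int* pm = mask.begin();
  int* pl = labels.begin();
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (pm[s] == 0 || pl[s] != 0) continue;
    ++next_label;
    pl[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int z = static_cast<int>(cur / (static_cast<R_xlen_t>(X) * Y));
      const int rem = static_cast<int>(cur - static_cast<R_xlen_t>(X) * Y * z);
      const int y = rem / X;
      const int x = rem - X * y;
      for (int dz = -1; dz <= 1; ++dz) {
        const int zz = z + dz;
        if (zz < 0 || zz >= Z) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= Y) continue;
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = x + dx;
            if (xx < 0 || xx >= X) continue;
            const R_xlen_t ni = xx + static_cast<R_xlen_t>(X) * (yy + static_cast<R_xlen_t>(Y) * zz);
            if (pm[ni] != 0 && pl[ni] == 0) {
              pl[ni] = next_label;
              stack.push_back(ni);
            }
          }
        }
      }
    }
  }
  return labels;
}

// Minimum-cost perfect matching on an n x m cost matrix with n <= m.
// Returns, for each row i, the 1-based column assigned to it.
// [[Rcpp::export]]
IntegerVector lap_cpp(NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n > m) stop("lap_cpp expects nrow <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, 0);
    do {
      used[j0] = 1;
      const int i0 = p[j0];
      int j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        const double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      const int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }
  IntegerVector assign(n);
  for (int j = 1; j <= m; ++j) {
    if (p[j] > 0) assign[p[j] - 1] = j;
  }
  return assign;
}
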