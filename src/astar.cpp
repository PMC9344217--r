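#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

// A* search for the minimum-cost left-to-right seam through a cost image.
//
// A path visits exactly one row per column, moving one column per step with a
// row jump of at most max_jump; its cost is the sum of visited node costs plus
// a smoothness penalty lambda * |row jump| per step. The heuristic is the
// suffix sum of per-column minimum node costs, which never overestimates the
// remaining cost (the smoothness penalty is non-negative), so the returned
// path is globally optimal for this cost function.
//
// [[Rcpp::export]]
List astar_path_cpp(NumericMatrix cost, double lambda, int max_jump) {
  const int H = cost.nrow(), W = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();

  // Admissible heuristic: h[c] = sum of column minima for columns > c.
  std::vector<double> colmin(W, INF), h(W + 1, 0.0);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (cost(r, c) < colmin[c]) colmin[c] = cost(r, c);
  for (int c = W - 1; c >= 0; --c) h[c] = h[c + 1] + colmin[c];

  std::vector<double> g(static_cast<size_t>(H) * W, INF);
  std::vector<int> parent(static_cast<size_t>(H) * W, -1);
  std::vector<char> closed(static_cast<size_t>(H) * W, 0);

  typedef std::pair<double, int> QN; // (f, node id = c * H + r)
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > open;

  for (int r = 0; r < H; ++r) {
    g[r] = cost(r, 0);
    open.push(QN(g[r] + h[1], r));
  }

  long expansions = 0;
  int goal = -1;
  while (!open.empty()) {
    QN top = open.top(); open.pop();
    int id = top.second;
    if (closed[id]) continue;
    closed[id] = 1;
    ++expansions;
    int c = id / H, r = id % H;
    if (c == W - 1) { goal = id; break; }
    int lo = r - max_jump < 0 ? 0 : r - max_jump;
    int hi = r + max_jump >= H ? H - 1 : r + max_jump;
    int cn = c + 1;
    for (int rn = lo; rn <= hi; ++rn) {
      int idn = cn * H + rn;
      if (closed[idn]) continue;
      double gn = g[id] + cost(rn, cn) + lambda * std::abs(rn - r);
      if (gn < g[idn]) {
        g[idn] = gn;
        parent[idn] = id;
        open.push(QN(gn + h[cn + 1], idn));
      }
    }
  }
  if (goal < 0) stop("A* failed to reach the last column");

  IntegerVector rows(W);
  int id = goal;
  for (int c = W - 1; c >= 0; --c) {
    rows[c] = id % H + 1; // 1-based for R
    id = parent[id];
  }
  return List::create(_["rows"] = rows, _["cost"] = g[goal],
                      _["expansions"] = expansions);
}
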