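#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Indexed 4-ary min-heap with decrease-key, keyed by dist[].  Grid Dijkstra
// relaxes each node's 16 neighbours many times; an indexed heap keeps the
// queue at <= n entries (no stale duplicates), which matters when the search
// is run tens of thousands of times inside the genetic algorithm.
struct Heap4 {
  std::vector<int> heap;   // node ids, heap order
  std::vector<int> pos;    // node id -> index in heap, -1 if absent
  const double *key;
  explicit Heap4(int n, const double *k) : pos(n, -1), key(k) {
    heap.reserve(256);
  }
  bool empty() const { return heap.empty(); }
  void sift_up(int i) {
    int v = heap[i];
    while (i > 0) {
      int p = (i - 1) >> 2;
      if (key[heap[p]] <= key[v]) break;
      heap[i] = heap[p]; pos[heap[i]] = i; i = p;
    }
    heap[i] = v; pos[v] = i;
  }
  void sift_down(int i) {
    int v = heap[i];
    const int n = (int)heap.size();
    for (;;) {
      int c = (i << 2) + 1;
      if (c >= n) break;
      int m = c;
      int hi = std::min(c + 4, n);
      for (int j = c + 1; j < hi; ++j)
        if (key[heap[j]] < key[heap[m]]) m = j;
      if (key[heap[m]] >= key[v]) break;
      heap[i] = heap[m]; pos[heap[i]] = i; i = m;
    }
    heap[i] = v; pos[v] = i;
  }
  void push_or_decrease(int v) {
    if (pos[v] < 0) { heap.push_back(v); sift_up((int)heap.size() - 1); }
    else sift_up(pos[v]);
  }
  int pop() {
    int top = heap[0];
    pos[top] = -1;
    int last = heap.back(); heap.pop_back();
    if (!heap.empty()) { heap[0] = last; pos[last] = 0; sift_down(0); }
    return top;
  }
};

// Single-source shortest path on a grid graph with 16-direction
// connectivity: the 8 queen neighbours plus the 8 chess knight offsets
// (step lengths 1, sqrt(2), sqrt(5) cells).  Edge weight between cells a
// and b is step_length * cell_size * (f(a) + f(b)) / 2, where
// f(c) = costs[class(c)] is the per-class friction of the cell.
//
// classes: dense 1-based class ids (NA = nodata), R column-major layout.
// costs:   per-class friction, length K, must be > 0 (validated upstream).
// origin:  0-based linear index of the source cell.
// targets: 0-based linear indices; when non-empty the search stops as soon
//          as every target has been finalised and only the target distances
//          are returned.  When empty the full grid is returned.
//
// Returns accumulated distance in the units of cell_size (km); NA for
// nodata cells, +Inf for cells unreachable from the origin.
// [[Rcpp::export]]
NumericVector dijkstra_grid_cpp(IntegerMatrix classes, NumericVector costs,
                                int origin, IntegerVector targets,
                                double cell_size) {
  const int nr = classes.nrow(), nc = classes.ncol();
  const long n = (long)nr * nc;

  static const int DR[16] = {-1, 1, 0, 0, -1, -1, 1, 1, -1, -1, 1, 1, -2, -2, 2, 2};
  static const int DC[16] = { 0, 0,-1, 1, -1,  1,-1, 1, -2,  2,-2, 2, -1,  1,-1, 1};
  const double s2 = std::sqrt(2.0), s5 = std::sqrt(5.0);
  double LEN[16];
  for (int k = 0; k < 4; ++k)  LEN[k] = cell_size;
  for (int k = 4; k < 8; ++k)  LEN[k] = s2 * cell_size;
  for (int k = 8; k < 16; ++k) LEN[k] = s5 * cell_size;

  std::vector<double> halff(n);
  std::vector<char> ok(n);
  const int *cl = INTEGER(classes);
  for (long i = 0; i < n; ++i) {
    if (cl[i] == NA_INTEGER) { ok[i] = 0; halff[i] = 0.0; }
    else { ok[i] = 1; halff[i] = 0.5 * costs[cl[i] - 1]; }
  }
  if (origin < 0 || origin >= n || !ok[origin])
    stop("origin cell is outside the grid or on nodata");

  std::vector<double> dist(n, R_PosInf);
  std::vector<char> done(n, 0);
  std::vector<char> is_target(n, 0);
  int remaining = 0;
  for (int t = 0; t < targets.size(); ++t) {
    int ti = targets[t];
    if (ti < 0 || ti >= n) stop("target index out of range");
    if (!is_target[ti]) { is_target[ti] = 1; ++remaining; }
  }
  const bool early = targets.size() > 0;

  Heap4 pq((int)n, dist.data());
  dist[origin] = 0.0;
  pq.push_or_decrease(origin);

  while (!pq.empty()) {
    const int u = pq.pop();
    done[u] = 1;
    if (early && is_target[u] && --remaining == 0) break;
    const int ur = u % nr, uc = u / nr;
    const double du = dist[u], hu = halff[u];
    const bool inner = ur >= 2 && ur < nr - 2 && uc >= 2 && uc < nc - 2;
    for (int k = 0; k < 16; ++k) {
      const int vr = ur + DR[k], vc = uc + DC[k];
      if (!inner && (vr < 0 || vr >= nr || vc < 0 || vc >= nc)) continue;
      const int v = vc * nr + vr;
      if (!ok[v] || done[v]) continue;
      const double dv = du + LEN[k] * (hu + halff[v]);
      if (dv < dist[v]) { dist[v] = dv; pq.push_or_decrease(v); }
    }
  }

  if (early) {
    NumericVector out(targets.size());
    for (int t = 0; t < targets.size(); ++t) out[t] = dist[targets[t]];
    return out;
  }
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = ok[i] ? dist[i] : NA_REAL;
  return out;
}
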