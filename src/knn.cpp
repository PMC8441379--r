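#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// kd-tree over 3D points; used by statistical outlier removal, where each
// point needs its mean distance to the k nearest other points.

namespace {

struct KDTree {
  const double* x; const double* y; const double* z;
  std::vector<int> idx;
  std::vector<int> axis;   // split axis per internal node, -1 for leaf marker
  int n;
  static const int LEAF = 16;

  struct Node { int lo, hi, left, right, ax; double split; };
  std::vector<Node> nodes;

  double coord(int i, int ax) const {
    return ax == 0 ? x[i] : (ax == 1 ? y[i] : z[i]);
  }

  int build(int lo, int hi) {
    Node nd; nd.lo = lo; nd.hi = hi; nd.left = -1; nd.right = -1; nd.ax = -1;
    nd.split = 0.0;
    int me = (int)nodes.size();
    nodes.push_back(nd);
    if (hi - lo <= LEAF) return me;
    // widest dimension
    double mn[3], mx[3];
    for (int a = 0; a < 3; ++a) { mn[a] = R_PosInf; mx[a] = R_NegInf; }
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double v = coord(idx[i], a);
        if (v < mn[a]) mn[a] = v;
        if (v > mx[a]) mx[a] = v;
      }
    int ax = 0;
    double w = mx[0] - mn[0];
    if (mx[1] - mn[1] > w) { w = mx[1] - mn[1]; ax = 1; }
    if (mx[2] - mn[2] > w) { w = mx[2] - mn[2]; ax = 2; }
    if (w <= 0) return me; // all points identical: leaf
    int mid = (lo + hi) / 2;
    const double* cx = (ax == 0) ? x : (ax == 1 ? y : z);
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [cx](int a, int b) { return cx[a] < cx[b]; });
    nodes[me].ax = ax;
    nodes[me].split = coord(idx[mid], ax);
    int left = build(lo, mid);
    int right = build(mid, hi);
    nodes[me].left = left;
    nodes[me].right = right;
    return me;
  }

  // bounded max-heap of squared distances
  void query(int node, int q, int k, std::vector<double>& heap) const {
    const Node& nd = nodes[node];
    if (nd.ax < 0) { // leaf
      for (int i = nd.lo; i < nd.hi; ++i) {
        int p = idx[i];
        if (p == q) continue;
        double dx = x[p]-x[q], dy = y[p]-y[q], dz = z[p]-z[q];
        double d2 = dx*dx + dy*dy + dz*dz;
        if ((int)heap.size() < k) {
          heap.push_back(d2);
          std::push_heap(heap.begin(), heap.end());
        } else if (d2 < heap.front()) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = d2;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double diff = coord(q, nd.ax) - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    query(near, q, k, heap);
    if ((int)heap.size() < k || diff * diff < heap.front())
      query(far, q, k, heap);
  }
};

} // namespace

// [[Rcpp::export]]
NumericVector cpp_knn_mean_dist(NumericMatrix pts, int k) {
  int n = pts.nrow();
  if (k < 1) stop("k must be >= 1");
  if (n <= k) stop("need more points than k");
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) { x[i] = pts(i,0); y[i] = pts(i,1); z[i] = pts(i,2); }
  KDTree t;
  t.x = x.data(); t.y = y.data(); t.z = z.data(); t.n = n;
  t.idx.resize(n);
  for (int i = 0; i < n; ++i) t.idx[i] = i;
  t.build(0, n);
  NumericVector out(n);
  std::vector<double> heap;
  heap.reserve(k + 1);
  for (int q = 0; q < n; ++q) {
    heap.clear();
    t.query(0, q, k, heap);
    double s = 0.0;
    for (size_t j = 0; j < heap.size(); ++j) s += std::sqrt(heap[j]);
    out[q] = s / (double)heap.size();
  }
  return out;
}
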