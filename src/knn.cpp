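#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact KNN lesion probability with deterministic tie handling.
//
// For each query row, the probability is the fraction of lesion-labelled
// training points among its k nearest neighbours under squared Euclidean
// distance. Ties on distance are broken in favour of the lower
// training-point index, so results are reproducible across platforms and
// identical to an exhaustive (distance, index)-lexicographic sort.
//
// The search uses a KD-tree over the training points. Squared distances are
// accumulated per point in ascending feature order, matching the
// floating-point summation order of a plain per-dimension accumulation, so
// results agree bitwise with a brute-force scan of the same data.

struct Pair {
  double d;
  int idx;
  bool operator<(const Pair &o) const {
    return d < o.d || (d == o.d && idx < o.idx);
  }
};

class KDTree {
public:
  KDTree(const std::vector<double> &pts, int n, int d)
    : pts_(pts), n_(n), d_(d) {
    perm_.resize(n);
    for (int i = 0; i < n; ++i) perm_[i] = i;
    nodes_.reserve(2 * n / LEAF + 4);
    root_ = build(0, n);
  }

  // fill out[0..k-1] with the k lexicographically smallest (dist2, index)
  void query(const double *q, int k, std::vector<Pair> &heap) const {
    heap.clear();
    k_ = k;
    q_ = q;
    search(root_, heap);
    std::sort(heap.begin(), heap.end());
  }

private:
  static const int LEAF = 24;
  struct Node {
    int split_dim;
    double split_val;
    int left, right;   // node ids, -1 for leaf
    int begin, end;    // range in perm_ for leaves
  };
  const std::vector<double> &pts_;
  int n_, d_, root_;
  std::vector<int> perm_;
  std::vector<Node> nodes_;
  mutable int k_;
  mutable const double *q_;

  double coord(int i, int j) const { return pts_[(size_t)j * n_ + i]; }

  int build(int begin, int end) {
    Node nd;
    nd.begin = begin; nd.end = end; nd.left = nd.right = -1;
    nd.split_dim = 0; nd.split_val = 0.0;
    int id = (int)nodes_.size();
    nodes_.push_back(nd);
    if (end - begin <= LEAF) return id;
    // split on the widest dimension at the median
    int best_dim = 0;
    double best_spread = -1.0;
    for (int j = 0; j < d_; ++j) {
      double lo = coord(perm_[begin], j), hi = lo;
      for (int i = begin + 1; i < end; ++i) {
        double v = coord(perm_[i], j);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
      if (hi - lo > best_spread) { best_spread = hi - lo; best_dim = j; }
    }
    if (best_spread <= 0.0) return id;  // all points identical: keep leaf
    int mid = (begin + end) / 2;
    std::nth_element(perm_.begin() + begin, perm_.begin() + mid,
                     perm_.begin() + end,
                     [&](int a, int b) {
                       double ca = coord(a, best_dim), cb = coord(b, best_dim);
                       return ca < cb || (ca == cb && a < b);
                     });
    double sv = coord(perm_[mid], best_dim);
    int l = build(begin, mid);
    int r = build(mid, end);
    nodes_[id].split_dim = best_dim;
    nodes_[id].split_val = sv;
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  // distance accumulated in ascending feature order (bitwise-stable)
  double dist2(int i) const {
    double s = 0.0;
    for (int j = 0; j < d_; ++j) {
      double diff = coord(i, j) - q_[j];
      s += diff * diff;
    }
    return s;
  }

  void consider(int i, std::vector<Pair> &heap) const {
    Pair p;
    p.d = dist2(i);
    p.idx = i;
    if ((int)heap.size() < k_) {
      heap.push_back(p);
      std::push_heap(heap.begin(), heap.end());
    } else if (p < heap.front()) {
      std::pop_heap(heap.begin(), heap.end());
      heap.back() = p;
      std::push_heap(heap.begin(), heap.end());
    }
  }

  void search(int id, std::vector<Pair> &heap) const {
    const Node &nd = nodes_[id];
    if (nd.left < 0) {
      for (int i = nd.begin; i < nd.end; ++i) consider(perm_[i], heap);
      return;
    }
    double delta = q_[nd.split_dim] - nd.split_val;
    int near = delta < 0 ? nd.left : nd.right;
    int far = delta < 0 ? nd.right : nd.left;
    search(near, heap);
    // the far side can only matter if the slab distance does not strictly
    // exceed the current worst retained distance (ties must be explored so
    // the lower-index rule can apply)
    double slab = delta * delta;
    if ((int)heap.size() < k_ || slab <= heap.front().d)
      search(far, heap);
  }
};

// train:  n_train x d feature matrix
// labels: integer 0/1 per training point (1 = lesion)
// query:  n_query x d feature matrix
// k:      neighbour count, 1 <= k <= n_train
// [[Rcpp::export(name = ".knn_prob_cpp")]]
NumericVector knn_prob_cpp(NumericMatrix train, IntegerVector labels,
                           NumericMatrix query, int k) {
  const int n = train.nrow(), d = train.ncol(), m = query.nrow();
  if (labels.size() != n) stop("labels length must match training rows");
  if (query.ncol() != d) stop("feature dimension mismatch");
  if (k < 1 || k > n) stop("k must lie in [1, number of training points]");

  std::vector<double> tr(train.begin(), train.end());
  KDTree tree(tr, n, d);
  NumericVector out(m);
  std::vector<Pair> heap;
  heap.reserve(k + 1);
  std::vector<double> q(d);

  for (int qi = 0; qi < m; ++qi) {
    for (int j = 0; j < d; ++j) q[j] = query(qi, j);
    tree.query(q.data(), k, heap);
    int lesion = 0;
    for (int i = 0; i < k; ++i) lesion += labels[heap[i].idx];
    out[qi] = (double)lesion / (double)k;
  }
  return out;
}
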