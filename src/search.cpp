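// Max-norm nearest-neighbour machinery for KSG-type estimators.
//
// Two backends behind one contract:
//  * brute force (the oracle): all-pairs distance scan
//  * k-d tree: median split on the widest box dimension, max-norm pruning
//
// All searches operate on one "chunk" (an embedded ensemble state space);
// every point doubles as a reference point. Points carry (repetition, time)
// tags; candidates in the SAME repetition within `theiler` samples of the
// reference are excluded from the search, as is the reference itself.
// Cross-repetition candidates are never excluded.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

namespace {

struct PointStore {
  int n, d;
  std::vector<double> x;  // row-major [n x d]
  const int* rep;
  const int* tim;
  int theiler;

  double coord(int i, int j) const { return x[(size_t)i * d + j]; }

  bool excluded(int ref, int cand) const {
    if (ref == cand) return true;
    if (rep[ref] == rep[cand] &&
        std::abs(tim[ref] - tim[cand]) <= theiler) return true;
    return false;
  }

  // max-norm distance with early exit once `bound` is exceeded
  double dist(int i, int j, double bound) const {
    const double* a = &x[(size_t)i * d];
    const double* b = &x[(size_t)j * d];
    double m = 0.0;
    for (int c = 0; c < d; ++c) {
      double v = std::fabs(a[c] - b[c]);
      if (v > m) {
        m = v;
        if (m >= bound) return m;
      }
    }
    return m;
  }
};

PointStore make_store(const NumericMatrix& X, const IntegerVector& rep,
                      const IntegerVector& tim, int theiler) {
  PointStore s;
  s.n = X.nrow();
  s.d = X.ncol();
  s.x.resize((size_t)s.n * s.d);
  for (int i = 0; i < s.n; ++i)
    for (int j = 0; j < s.d; ++j) s.x[(size_t)i * s.d + j] = X(i, j);
  s.rep = rep.begin();
  s.tim = tim.begin();
  s.theiler = theiler;
  return s;
}

// ---- fixed-size k-best heap (k is small; insertion into sorted array) ----
struct KBest {
  int k;
  std::vector<double> d;  // ascending
  std::vector<int> idx;
  explicit KBest(int k_) : k(k_), d(k_, std::numeric_limits<double>::infinity()),
                           idx(k_, -1) {}
  double worst() const { return d[k - 1]; }
  void offer(double dist, int i) {
    if (dist >= d[k - 1]) return;
    int pos = k - 1;
    while (pos > 0 && d[pos - 1] > dist) {
      d[pos] = d[pos - 1];
      idx[pos] = idx[pos - 1];
      --pos;
    }
    d[pos] = dist;
    idx[pos] = i;
  }
  int filled() const {
    int c = 0;
    for (int i = 0; i < k; ++i) c += (idx[i] >= 0);
    return c;
  }
};

// ------------------------------ k-d tree ---------------------------------
struct KdNode {
  int left = -1, right = -1;   // children (node indices), -1 for leaf
  int begin = 0, end = 0;      // leaf: range into perm
  int split_dim = -1;
  double split_val = 0.0;
  std::vector<double> lo, hi;  // bounding box
};

struct KdTree {
  const PointStore* s;
  std::vector<int> perm;
  std::vector<KdNode> nodes;
  static const int LEAF = 24;

  void build(const PointStore& store) {
    s = &store;
    perm.resize(store.n);
    for (int i = 0; i < store.n; ++i) perm[i] = i;
    nodes.reserve(2 * store.n / LEAF + 8);
    build_node(0, store.n);
  }

  int build_node(int begin, int end) {
    int id = (int)nodes.size();
    nodes.push_back(KdNode());
    KdNode& nd = nodes[id];
    nd.begin = begin;
    nd.end = end;
    int d = s->d;
    nd.lo.assign(d, std::numeric_limits<double>::infinity());
    nd.hi.assign(d, -std::numeric_limits<double>::infinity());
    for (int i = begin; i < end; ++i) {
      int p = perm[i];
      for (int j = 0; j < d; ++j) {
        double v = s->coord(p, j);
        if (v < nd.lo[j]) nd.lo[j] = v;
        if (v > nd.hi[j]) nd.hi[j] = v;
      }
    }
    if (end - begin <= LEAF) return id;
    // split widest dimension at the median
    int sd = 0;
    double w = -1.0;
    for (int j = 0; j < d; ++j) {
      double e = nd.hi[j] - nd.lo[j];
      if (e > w) { w = e; sd = j; }
    }
    if (w <= 0.0) return id;  // all points identical: leaf
    int mid = (begin + end) / 2;
    std::nth_element(perm.begin() + begin, perm.begin() + mid,
                     perm.begin() + end, [&](int a, int b) {
                       return s->coord(a, sd) < s->coord(b, sd);
                     });
    double sv = s->coord(perm[mid], sd);
    // record split, then recurse (note: push_back may reallocate `nodes`,
    // so do not hold the reference across recursion)
    nodes[id].split_dim = sd;
    nodes[id].split_val = sv;
    int l = build_node(begin, mid);
    int r = build_node(mid, end);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  // max-norm distance from query point to a node's bounding box
  double box_dist(const KdNode& nd, int q) const {
    double m = 0.0;
    for (int j = 0; j < s->d; ++j) {
      double v = s->coord(q, j);
      double e = (v < nd.lo[j]) ? nd.lo[j] - v : (v > nd.hi[j] ? v - nd.hi[j] : 0.0);
      if (e > m) m = e;
    }
    return m;
  }

  void knn_query(int q, KBest& kb) const { knn_node(0, q, kb); }

  void knn_node(int id, int q, KBest& kb) const {
    const KdNode& nd = nodes[id];
    if (box_dist(nd, q) >= kb.worst()) return;
    if (nd.left < 0) {
      for (int i = nd.begin; i < nd.end; ++i) {
        int p = perm[i];
        if (s->excluded(q, p)) continue;
        double dd = s->dist(q, p, kb.worst());
        kb.offer(dd, p);
      }
      return;
    }
    // visit nearer child first
    double qv = s->coord(q, nd.split_dim);
    int first = (qv < nd.split_val) ? nd.left : nd.right;
    int second = (first == nd.left) ? nd.right : nd.left;
    knn_node(first, q, kb);
    knn_node(second, q, kb);
  }

  // count points with max-norm distance STRICTLY less than r
  long count_query(int q, double r) const { return count_node(0, q, r); }

  long count_node(int id, int q, double r) const {
    const KdNode& nd = nodes[id];
    if (box_dist(nd, q) >= r) return 0;
    if (nd.left < 0) {
      long c = 0;
      for (int i = nd.begin; i < nd.end; ++i) {
        int p = perm[i];
        if (s->excluded(q, p)) continue;
        if (s->dist(q, p, r) < r) ++c;
      }
      return c;
    }
    return count_node(nd.left, q, r) + count_node(nd.right, q, r);
  }
};

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_knn_dist(NumericMatrix X, int k, IntegerVector rep,
                           IntegerVector tim, int theiler, bool tree) {
  PointStore s = make_store(X, rep, tim, theiler);
  NumericVector out(s.n);
  if (tree) {
    KdTree t;
    t.build(s);
    for (int q = 0; q < s.n; ++q) {
      KBest kb(k);
      t.knn_query(q, kb);
      if (kb.filled() < k)
        stop("knn_search: fewer than k=%d admissible neighbours for point %d",
             k, q + 1);
      out[q] = kb.worst();
    }
  } else {
    for (int q = 0; q < s.n; ++q) {
      KBest kb(k);
      for (int p = 0; p < s.n; ++p) {
        if (s.excluded(q, p)) continue;
        kb.offer(s.dist(q, p, kb.worst()), p);
      }
      if (kb.filled() < k)
        stop("knn_search: fewer than k=%d admissible neighbours for point %d",
             k, q + 1);
      out[q] = kb.worst();
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_knn_idx(NumericMatrix X, int k, IntegerVector rep,
                          IntegerVector tim, int theiler, bool tree) {
  PointStore s = make_store(X, rep, tim, theiler);
  IntegerMatrix out(s.n, k);
  KdTree t;
  if (tree) t.build(s);
  for (int q = 0; q < s.n; ++q) {
    KBest kb(k);
    if (tree) {
      t.knn_query(q, kb);
    } else {
      for (int p = 0; p < s.n; ++p) {
        if (s.excluded(q, p)) continue;
        kb.offer(s.dist(q, p, kb.worst()), p);
      }
    }
    if (kb.filled() < k)
      stop("knn_search: fewer than k=%d admissible neighbours for point %d",
           k, q + 1);
    for (int j = 0; j < k; ++j) out(q, j) = kb.idx[j] + 1;  // 1-based
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_range_count(NumericMatrix X, NumericVector radii,
                              IntegerVector rep, IntegerVector tim,
                              int theiler, bool tree) {
  PointStore s = make_store(X, rep, tim, theiler);
  if ((int)radii.size() != s.n) stop("radii must align with points");
  IntegerVector out(s.n);
  if (tree) {
    KdTree t;
    t.build(s);
    for (int q = 0; q < s.n; ++q) {
      double r = radii[q];
      if (r < 0) stop("range_count: negative radius for point %d", q + 1);
      out[q] = (int)t.count_query(q, r);
    }
  } else {
    for (int q = 0; q < s.n; ++q) {
      double r = radii[q];
      if (r < 0) stop("range_count: negative radius for point %d", q + 1);
      long c = 0;
      for (int p = 0; p < s.n; ++p) {
        if (s.excluded(q, p)) continue;
        if (s.dist(q, p, r) < r) ++c;
      }
      out[q] = (int)c;
    }
  }
  return out;
}
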