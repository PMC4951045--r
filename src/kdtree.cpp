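#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Static balanced k-d tree over 3-D points.  Query returns, for each probe,
// the index of the nearest stored point; exact ties are broken toward the
// lowest stored index so results match a first-wins linear scan.

struct KDTree {
  std::vector<double> x, y, z;  // points in original order
  std::vector<int> perm;        // tree-ordered indices into x/y/z
  std::vector<int> lo, hi;      // node ranges into perm
  std::vector<int> left, right, axis;
  int root;
  int n;

  int build(int b, int e, int depth) {
    if (b >= e) return -1;
    int ax = depth % 3;
    const std::vector<double>& c = ax == 0 ? x : (ax == 1 ? y : z);
    int m = (b + e) / 2;
    std::nth_element(perm.begin() + b, perm.begin() + m, perm.begin() + e,
                     [&](int a, int bb) { return c[a] < c[bb]; });
    int node = (int)axis.size();
    axis.push_back(ax);
    lo.push_back(b); hi.push_back(e);
    left.push_back(-1); right.push_back(-1);
    // placeholder; children filled after recursion
    int l = build(b, m, depth + 1);
    int r = build(m + 1, e, depth + 1);
    left[node] = l; right[node] = r;
    return node;
  }

  void query(double px, double py, double pz, int node,
             double& bestd2, int& besti) const {
    if (node < 0) return;
    int m = (lo[node] + hi[node]) / 2;
    int i = perm[m];
    double dx = x[i] - px, dy = y[i] - py, dz = z[i] - pz;
    double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < bestd2 || (d2 == bestd2 && i < besti)) { bestd2 = d2; besti = i; }
    int ax = axis[node];
    double delta = (ax == 0 ? x[i] - px : (ax == 1 ? y[i] - py : z[i] - pz));
    int near = delta > 0 ? left[node] : right[node];
    int far = delta > 0 ? right[node] : left[node];
    query(px, py, pz, near, bestd2, besti);
    // visit far side on exact-boundary ties too, so index tie-break is global
    if (delta * delta <= bestd2) query(px, py, pz, far, bestd2, besti);
  }
};

static void kdtree_finalizer(KDTree* t) { delete t; }

// [[Rcpp::export(name = ".kdtree_build")]]
SEXP kdtree_build(NumericMatrix pts) {
  KDTree* t = new KDTree();
  int n = pts.nrow();
  t->n = n;
  t->x.resize(n); t->y.resize(n); t->z.resize(n);
  t->perm.resize(n);
  for (int i = 0; i < n; ++i) {
    t->x[i] = pts(i, 0); t->y[i] = pts(i, 1); t->z[i] = pts(i, 2);
    t->perm[i] = i;
  }
  t->root = t->build(0, n, 0);
  XPtr<KDTree> p(t, true);
  return p;
}

// [[Rcpp::export(name = ".kdtree_query")]]
List kdtree_query(SEXP tree, NumericMatrix probes) {
  XPtr<KDTree> t(tree);
  int m = probes.nrow();
  IntegerVector idx(m);
  NumericVector dist(m);
  for (int j = 0; j < m; ++j) {
    double bestd2 = R_PosInf;
    int besti = t->n;
    t->query(probes(j, 0), probes(j, 1), probes(j, 2), t->root, bestd2, besti);
    idx[j] = besti + 1;  // 1-based
    dist[j] = std::sqrt(bestd2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
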