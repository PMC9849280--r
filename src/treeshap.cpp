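#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Interventional Shapley values for a regression tree ensemble.
//
// For a foreground row x and one background row z, a coalition S follows
// the branch chosen by x for split features in S and by z otherwise. Each
// leaf's reachable coalitions form a cube {S : S >= Xset, S /\ Zset = 0},
// where Xset collects path features on which x and z diverge and the path
// follows x, and Zset those where it follows z. The Shapley contribution of
// the leaf value v is then
//   +v * (a-1)! b! / (a+b)!  for every feature in Xset  (a = |Xset|)
//   -v * a! (b-1)! / (a+b)!  for every feature in Zset  (b = |Zset|),
// features off the path being null players. Attributions are averaged over
// the background rows and summed over trees (ensemble prediction = mean
// over trees, so each tree contributes value/n_trees).

static double W_pos(int a, int b) {
  // (a-1)! b! / (a+b)!
  double w = 1.0;
  for (int i = 1; i <= b; ++i) w *= (double)i / (double)(a + i);
  return w / (double)a;
}

struct Tree {
  IntegerVector left, right, splitvar;
  NumericVector splitval, pred;
};

static void walk(const Tree& tr, int node,
                 const NumericVector& x, const NumericVector& z,
                 std::vector<int>& state,  // 0 none, 1 in-S, 2 not-in-S
                 std::vector<int>& path, int a, int b,
                 double scale, std::vector<double>& phi, double& phi0) {
  int l = tr.left[node], r = tr.right[node];
  if (l < 0) {  // terminal
    double v = tr.pred[node] * scale;
    if (a == 0 && b == 0) {
      phi0 += v;  // reached by every coalition incl. the empty one
      return;
    }
    if (a == 0) {
      // reachable only when all Zset features are absent: contributes to
      // v(empty set) as well
      phi0 += v;
    }
    double wp = (a > 0) ? W_pos(a, b) : 0.0;
    double wn = (b > 0) ? W_pos(b, a) : 0.0;
    for (size_t i = 0; i < path.size(); ++i) {
      int f = path[i];
      if (state[f] == 1) phi[f] += v * wp;
      else if (state[f] == 2) phi[f] -= v * wn;
    }
    return;
  }
  int f = tr.splitvar[node];
  bool xl = x[f] <= tr.splitval[node];
  bool zl = z[f] <= tr.splitval[node];
  if (xl == zl) {  // no constraint added
    walk(tr, xl ? l : r, x, z, state, path, a, b, scale, phi, phi0);
    return;
  }
  int prev = state[f];
  bool onpath = (prev != 0);
  // branch where x goes: requires f in S
  if (prev != 2) {
    state[f] = 1;
    if (!onpath) path.push_back(f);
    walk(tr, xl ? l : r, x, z, state, path,
         a + (prev == 1 ? 0 : 1), b, scale, phi, phi0);
    if (!onpath) path.pop_back();
    state[f] = prev;
  }
  // branch where z goes: requires f not in S
  if (prev != 1) {
    state[f] = 2;
    if (!onpath) path.push_back(f);
    walk(tr, zl ? l : r, x, z, state, path,
         a, b + (prev == 2 ? 0 : 1), scale, phi, phi0);
    if (!onpath) path.pop_back();
    state[f] = prev;
  }
}

// trees: list of lists with integer vectors left, right, splitvar (0-based,
// -1 for terminal) and numeric splitval, pred. X_explain / X_bg: matrices
// with columns in the training feature order.
// [[Rcpp::export(name = ".tree_shap_cpp")]]
List tree_shap_cpp(List trees, NumericMatrix X_explain, NumericMatrix X_bg) {
  int M = X_explain.ncol();
  int ne = X_explain.nrow(), nb = X_bg.nrow(), nt = trees.size();
  NumericMatrix phi(ne, M);
  NumericVector phi0(ne);
  std::vector<Tree> forest(nt);
  for (int t = 0; t < nt; ++t) {
    List tl = trees[t];
    forest[t].left = tl["left"];
    forest[t].right = tl["right"];
    forest[t].splitvar = tl["splitvar"];
    forest[t].splitval = tl["splitval"];
    forest[t].pred = tl["pred"];
  }
  double scale = 1.0 / ((double)nt * (double)nb);
  for (int i = 0; i < ne; ++i) {
    NumericVector x = X_explain(i, _);
    std::vector<double> acc(M, 0.0);
    double base = 0.0;
    std::vector<int> state(M, 0);
    std::vector<int> path;
    for (int bi = 0; bi < nb; ++bi) {
      NumericVector z = X_bg(bi, _);
      for (int t = 0; t < nt; ++t) {
        walk(forest[t], 0, x, z, state, path, 0, 0, scale, acc, base);
      }
    }
    for (int j = 0; j < M; ++j) phi(i, j) = acc[j];
    phi0[i] = base;
  }
  return List::create(_["phi"] = phi, _["phi0"] = phi0);
}
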