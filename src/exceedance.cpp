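#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fenwick (binary indexed) tree over dense p1 ranks.
struct Fenwick {
  std::vector<int> t;
  explicit Fenwick(int n) : t(n + 1, 0) {}
  void add(int i) { for (++i; i < (int)t.size(); i += i & -i) t[i]++; }
  int prefix(int i) const {  // count of inserted ranks <= i
    int s = 0;
    for (++i; i > 0; i -= i & -i) s += t[i];
    return s;
  }
};

// For each row i of (p1, p2): n_cond = #{j : p2_j <= p2_i} and
// n_joint = #{j : p1_j <= p1_i and p2_j <= p2_i}, comparisons inclusive.
// Sweep rows in increasing p2, inserting tied-p2 groups wholesale before
// querying them, so every row counts itself. O(M log M).
// [[Rcpp::export]]
List exceedance_counts_sweep(NumericVector p1, NumericVector p2) {
  const int m = p1.size();
  if (p2.size() != m) stop("p1 and p2 must have equal length");

  // dense ranks of p1 (ties share a rank)
  std::vector<int> ord(m);
  for (int i = 0; i < m; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return p1[a] < p1[b]; });
  std::vector<int> rank1(m);
  int r = -1;
  double prev = R_NegInf;
  for (int k = 0; k < m; ++k) {
    if (k == 0 || p1[ord[k]] != prev) { ++r; prev = p1[ord[k]]; }
    rank1[ord[k]] = r;
  }
  const int nr = r + 1;

  // sweep in increasing p2
  std::vector<int> o2(m);
  for (int i = 0; i < m; ++i) o2[i] = i;
  std::sort(o2.begin(), o2.end(),
            [&](int a, int b) { return p2[a] < p2[b]; });

  IntegerVector n_cond(m), n_joint(m);
  Fenwick fw(nr);
  int k = 0;
  while (k < m) {
    int k2 = k;
    while (k2 < m && p2[o2[k2]] == p2[o2[k]]) ++k2;   // tied-p2 group [k, k2)
    for (int t = k; t < k2; ++t) fw.add(rank1[o2[t]]);
    for (int t = k; t < k2; ++t) {
      n_cond[o2[t]] = k2;
      n_joint[o2[t]] = fw.prefix(rank1[o2[t]]);
    }
    k = k2;
  }
  return List::create(_["n_cond"] = n_cond, _["n_joint"] = n_joint);
}
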