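#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass 8-connectivity connected-component labeling with union-find.
// mask: logical matrix (column-major). Returns integer matrix of labels
// (0 = background), labels consecutive from 1 in first-touch order.

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export(name = ".label_components_8")]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 0;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // previously visited 8-neighbours: (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int nbr[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int k = 0; k < 4; ++k) {
        int rr = nbr[k][0], cc = nbr[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(parent, best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // resolve and relabel consecutively
  std::vector<int> newlab(next + 1, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (newlab[root] == 0) newlab[root] = ++out;
      lab(r, c) = newlab[root];
    }
  }
  lab.attr("n_labels") = out;
  return lab;
}
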