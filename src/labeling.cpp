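#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[ra < rb ? rb : ra] = (ra < rb ? ra : rb);
}

//' @noRd
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // index 0 unused (background)

  // First pass, column-major raster: neighbours already visited are
  // (r-1, c), (r, c-1) and for 8-connectivity (r-1, c-1), (r+1, c-1).
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      int neigh[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c)) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && mask(r, c - 1)) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && mask(r - 1, c - 1)) neigh[nn++] = lab(r - 1, c - 1);
        if (r + 1 < nr && mask(r + 1, c - 1)) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int k = 0; k < nn; ++k)
        if (best == 0 || neigh[k] < best) best = neigh[k];
      if (best == 0) {
        int id = (int) parent.size();
        parent.push_back(id);
        lab(r, c) = id;
      } else {
        lab(r, c) = best;
        for (int k = 0; k < nn; ++k) uf_union(parent, best, neigh[k]);
      }
    }
  }

  // Second pass: resolve labels and renumber 1..k by first occurrence.
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = lab(r, c);
      if (id == 0) continue;
      int root = uf_find(parent, id);
      if (remap[root] == 0) remap[root] = ++next;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
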