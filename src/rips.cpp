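#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Vietoris-Rips persistence on a distance matrix, dimensions 0 and 1.
//
// Dimension 0: Kruskal/union-find over edges sorted by (weight, i, j).
// The merge edges are exactly the Euclidean minimum spanning tree; each
// merge emits a bar (0, w).  The elder rule with ties broken towards the
// component holding the smallest vertex index decides which component
// label survives (the diagram itself is unaffected since all vertices are
// born at scale 0).
//
// Dimension 1: standard boundary-matrix reduction over GF(2).  Triangle
// columns are expressed in the basis of filtration-ordered edges; the low
// entry of a reduced non-zero column pairs a (positive) edge with the
// triangle, giving a bar (w_edge, w_triangle).  Positive edges never
// appearing as a low within max_scale yield infinite bars.

struct EdgeRec {
  double w;
  int i, j; // 0-based, i < j
};

struct TriRec {
  double w;
  int i, j, k; // 0-based, i < j < k
};

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// [[Rcpp::export]]
List rips_cpp(NumericMatrix D, double maxScale, int maxDim) {
  const int n = D.nrow();
  if (n < 1) stop("empty point set");

  std::vector<EdgeRec> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = D(i, j);
      if (w <= maxScale) edges.push_back({w, i, j});
    }
  std::sort(edges.begin(), edges.end(), [](const EdgeRec& a, const EdgeRec& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  const int nE = (int)edges.size();

  // --- dimension 0 ---
  std::vector<int> parent(n), minv(n);
  for (int i = 0; i < n; ++i) { parent[i] = i; minv[i] = i; }
  std::vector<double> h0death;
  std::vector<int> mst_i, mst_j;
  std::vector<double> mst_w;
  std::vector<char> isMerge(nE, 0);
  for (int e = 0; e < nE; ++e) {
    int ra = uf_find(parent, edges[e].i);
    int rb = uf_find(parent, edges[e].j);
    if (ra != rb) {
      // elder rule: survivor is the component with the smaller minimal vertex
      int survivor = (minv[ra] <= minv[rb]) ? ra : rb;
      int dying = (survivor == ra) ? rb : ra;
      parent[dying] = survivor;
      minv[survivor] = std::min(minv[ra], minv[rb]);
      h0death.push_back(edges[e].w);
      mst_i.push_back(edges[e].i + 1);
      mst_j.push_back(edges[e].j + 1);
      mst_w.push_back(edges[e].w);
      isMerge[e] = 1;
    }
  }

  std::vector<double> h1birth, h1death, h1infbirth;

  if (maxDim >= 1 && n >= 3) {
    // lookup from vertex pair to filtration-ordered edge index
    std::vector<int> eidx((size_t)n * n, -1);
    for (int e = 0; e < nE; ++e)
      eidx[(size_t)edges[e].i * n + edges[e].j] = e;

    std::vector<TriRec> tris;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double dij = D(i, j);
        if (dij > maxScale) continue;
        for (int k = j + 1; k < n; ++k) {
          double w = std::max(dij, std::max(D(i, k), D(j, k)));
          if (w <= maxScale) tris.push_back({w, i, j, k});
        }
      }
    // stable sort keeps lexicographic order within equal weights
    std::stable_sort(tris.begin(), tris.end(),
                     [](const TriRec& a, const TriRec& b) { return a.w < b.w; });

    std::unordered_map<int, int> lowToCol; // edge row -> column id
    std::vector<std::vector<int>> cols(tris.size());
    std::vector<char> edgePaired(nE, 0);

    std::vector<int> tmp;
    for (size_t t = 0; t < tris.size(); ++t) {
      std::vector<int> col = {
        eidx[(size_t)tris[t].i * n + tris[t].j],
        eidx[(size_t)tris[t].i * n + tris[t].k],
        eidx[(size_t)tris[t].j * n + tris[t].k]};
      std::sort(col.begin(), col.end());
      while (!col.empty()) {
        int low = col.back();
        auto it = lowToCol.find(low);
        if (it == lowToCol.end()) break;
        const std::vector<int>& other = cols[it->second];
        tmp.clear();
        std::set_symmetric_difference(col.begin(), col.end(), other.begin(),
                                      other.end(), std::back_inserter(tmp));
        col.swap(tmp);
      }
      if (!col.empty()) {
        int low = col.back();
        lowToCol[low] = (int)t;
        cols[t] = std::move(col);
        edgePaired[low] = 1;
        double b = edges[low].w, d = tris[t].w;
        if (d > b) {
          h1birth.push_back(b);
          h1death.push_back(d);
        }
      }
      if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    for (int e = 0; e < nE; ++e)
      if (!isMerge[e] && !edgePaired[e]) h1infbirth.push_back(edges[e].w);
  }

  return List::create(
      _["h0death"] = wrap(h0death),
      _["mst_i"] = wrap(mst_i),
      _["mst_j"] = wrap(mst_j),
      _["mst_w"] = wrap(mst_w),
      _["h1birth"] = wrap(h1birth),
      _["h1death"] = wrap(h1death),
      _["h1infbirth"] = wrap(h1infbirth));
}
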