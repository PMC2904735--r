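#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Graphlet degree vector counting by ESU enumeration.
//
// Enumerates every connected induced subgraph on 2..5 nodes exactly once
// (Wernicke's ESU: grow from each root using only higher-numbered nodes and
// exclusive neighbourhoods), encodes each subgraph as an edge bit-mask over
// node positions in insertion order, and resolves the automorphism orbit of
// every position through the catalog's per-mask lookup tables.  The mask bit
// order matches the R side: node at position j (0-based) contributes bits
// j*(j-1)/2 .. j*(j-1)/2 + j - 1 for its adjacency to positions 0..j-1, so
// masks grow incrementally as nodes are appended.

namespace {

struct Esu {
  int n;
  const std::vector<std::vector<int> > &nbr;
  std::vector<uint64_t> bits; // dense adjacency bitset (row-major)
  int words;
  bool dense;
  const int *look[6];         // orbit lookup per size k (2..5)
  NumericMatrix &counts;
  std::vector<int> sub;       // current subgraph, insertion order
  std::vector<int> submask;   // cumulative edge mask at each depth
  std::vector<char> visited;  // in subgraph, or already offered as extension
  int root;

  Esu(int n_, const std::vector<std::vector<int> > &nbr_, NumericMatrix &counts_)
    : n(n_), nbr(nbr_), counts(counts_), sub(5), submask(6, 0), visited(n_, 0) {
    dense = n <= 8192;
    if (dense) {
      words = (n + 63) / 64;
      bits.assign((size_t)n * words, 0ULL);
      for (int v = 0; v < n; ++v)
        for (size_t i = 0; i < nbr[v].size(); ++i) {
          int u = nbr[v][i];
          bits[(size_t)v * words + u / 64] |= 1ULL << (u % 64);
        }
    }
  }

  bool adjacent(int u, int v) const {
    if (dense) return (bits[(size_t)u * words + v / 64] >> (v % 64)) & 1ULL;
    const std::vector<int> &a = nbr[u];
    return std::binary_search(a.begin(), a.end(), v);
  }

  void record(int depth) { // depth = current subgraph size, >= 2
    const int *L = look[depth];
    int mask = submask[depth];
    for (int p = 0; p < depth; ++p) {
      int orb = L[(size_t)p * (1 << (depth * (depth - 1) / 2)) + mask];
      counts(sub[p], orb) += 1.0;
    }
  }

  void extend(std::vector<int> &ext, int depth) {
    // ext holds candidate nodes, each adjacent to the current subgraph;
    // candidate i's branch may only re-use candidates i+1.. (never earlier
    // ones), which is what makes every connected subset appear exactly once
    for (size_t i = 0; i < ext.size(); ++i) {
      int w = ext[i];
      // append w at position `depth`
      int wb = 0;
      for (int p = 0; p < depth; ++p)
        if (adjacent(w, sub[p])) wb |= 1 << p;
      sub[depth] = w;
      submask[depth + 1] = submask[depth] | (wb << (depth * (depth - 1) / 2));
      record(depth + 1);
      if (depth + 1 < 5) {
        // extension set: remaining candidates + exclusive neighbours of w
        // (w's neighbours not already in, or adjacent to, the subgraph);
        // the marks are scoped to w's branch only
        std::vector<int> ext2(ext.begin() + i + 1, ext.end());
        std::vector<int> mark;
        for (size_t t = 0; t < nbr[w].size(); ++t) {
          int u = nbr[w][t];
          if (u > root && !visited[u]) {
            visited[u] = 1;
            mark.push_back(u);
            ext2.push_back(u);
          }
        }
        extend(ext2, depth + 1);
        for (size_t t = 0; t < mark.size(); ++t) visited[mark[t]] = 0;
      }
    }
  }

  void run() {
    for (int v = 0; v < n; ++v) {
      root = v;
      sub[0] = v;
      submask[1] = 0;
      visited[v] = 1;
      std::vector<int> ext;
      for (size_t t = 0; t < nbr[v].size(); ++t) {
        int u = nbr[v][t];
        if (u > v) { visited[u] = 1; ext.push_back(u); }
      }
      extend(ext, 1);
      visited[v] = 0;
      for (size_t t = 0; t < ext.size(); ++t) visited[ext[t]] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix esu_gdv_counts(int n, List adj, List lookups) {
  std::vector<std::vector<int> > nbr(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector a = adj[v];
    nbr[v].assign(a.begin(), a.end());
    std::sort(nbr[v].begin(), nbr[v].end());
  }
  NumericMatrix counts(n, 73);
  Esu esu(n, nbr, counts);
  // lookup tables arrive as (2^(C(k,2)) x k) integer matrices, column-major
  std::vector<IntegerMatrix> keep;
  for (int k = 2; k <= 5; ++k) {
    IntegerMatrix L = lookups[k - 2];
    keep.push_back(L);
    esu.look[k] = INTEGER(keep.back());
  }
  esu.run();
  return counts;
}
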