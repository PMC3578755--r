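#include <Rcpp.h>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Degree-preserving randomization of an intermodular edge set by
// repeated double-edge swaps. Each round starts from the original edge
// set and proposes nSwaps swaps; a proposal is rejected (not re-drawn)
// if it would create a self-loop, a duplicate edge, or an edge whose
// endpoints share a module. Proposals are symmetric, so the stationary
// distribution is uniform over the reachable valid configurations.
// Uses R's RNG: results are reproducible under set.seed().

static inline long long edge_key(int a, int b, int n) {
  if (a > b) std::swap(a, b);
  return (long long)a * n + b;
}

static inline bool share_module(const std::vector<int>& x,
                                const std::vector<int>& y) {
  size_t i = 0, j = 0;
  while (i < x.size() && j < y.size()) {
    if (x[i] == y[j]) return true;
    if (x[i] < y[j]) ++i; else ++j;
  }
  return false;
}

// [[Rcpp::export(name = ".rewireRoundsCpp")]]
List rewireRoundsCpp(IntegerMatrix edges, List membership, int nProteins,
                     int nRounds, double swapsPerEdge) {
  const int m = edges.nrow();
  std::vector<std::vector<int>> memb(nProteins);
  for (int p = 0; p < nProteins; ++p) {
    IntegerVector mv = membership[p];
    memb[p].assign(mv.begin(), mv.end());
    std::sort(memb[p].begin(), memb[p].end());
  }
  const int nSwaps = (int)std::ceil(swapsPerEdge * m);
  List out(nRounds);
  for (int r = 0; r < nRounds; ++r) {
    std::vector<int> ea(m), eb(m);
    std::unordered_set<long long> present;
    present.reserve(m * 2);
    for (int i = 0; i < m; ++i) {
      ea[i] = edges(i, 0);
      eb[i] = edges(i, 1);
      present.insert(edge_key(ea[i], eb[i], nProteins));
    }
    if (m >= 2) {
      for (int s = 0; s < nSwaps; ++s) {
        int i = (int)(unif_rand() * m); if (i >= m) i = m - 1;
        int j = (int)(unif_rand() * m); if (j >= m) j = m - 1;
        if (i == j) continue;
        int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
        int na1, nb1, na2, nb2;
        if (unif_rand() < 0.5) { na1 = a; nb1 = d; na2 = c; nb2 = b; }
        else                   { na1 = a; nb1 = c; na2 = b; nb2 = d; }
        if (na1 == nb1 || na2 == nb2) continue;
        long long k1 = edge_key(na1, nb1, nProteins);
        long long k2 = edge_key(na2, nb2, nProteins);
        if (k1 == k2) continue;
        if (present.count(k1) || present.count(k2)) continue;
        if (share_module(memb[na1], memb[nb1]) ||
            share_module(memb[na2], memb[nb2])) continue;
        present.erase(edge_key(a, b, nProteins));
        present.erase(edge_key(c, d, nProteins));
        present.insert(k1);
        present.insert(k2);
        ea[i] = na1; eb[i] = nb1;
        ea[j] = na2; eb[j] = nb2;
      }
    }
    IntegerMatrix em(m, 2);
    for (int i = 0; i < m; ++i) {
      em(i, 0) = std::min(ea[i], eb[i]);
      em(i, 1) = std::max(ea[i], eb[i]);
    }
    out[r] = em;
  }
  return out;
}
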