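#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Cycle decomposition of the union of two perfect matchings on the same
// vertex set.  Vertices are 1..N in canonical (sorted label) order; mate1 /
// mate2 give the partner of each vertex in either matching, w1 / w2 the
// weight of the incident edge (stored at both endpoints).  Traversal is
// deterministic: each cycle starts at its smallest unvisited vertex and
// follows its genome-1 edge first, so cycle indices are reproducible.
// [[Rcpp::export]]
List bg_decompose_cpp(IntegerVector mate1, IntegerVector mate2,
                      NumericVector w1, NumericVector w2) {
  const int N = mate1.size();
  if (mate2.size() != N || w1.size() != N || w2.size() != N)
    stop("matchings must live on the same vertex set");
  std::vector<int> cyc(N, -1);
  IntegerVector verts(N);            // vertices in traversal order
  std::vector<int> sizes;            // edges per cycle (= vertices per cycle)
  std::vector<double> cw1, cw2;
  int c = 0, pos = 0;
  for (int s = 0; s < N; ++s) {
    if (cyc[s] != -1) continue;
    int len = 0;
    double a = 0.0, b = 0.0;
    int v = s;
    do {
      int u = mate1[v] - 1;          // genome-1 edge v--u
      a += w1[v];
      cyc[v] = c; cyc[u] = c;
      verts[pos++] = v + 1;
      verts[pos++] = u + 1;
      len += 2;                      // one g1 edge + one g2 edge per hop
      b += w2[u];                    // genome-2 edge u--mate2[u]
      v = mate2[u] - 1;
    } while (v != s);
    sizes.push_back(len);
    cw1.push_back(a);
    cw2.push_back(b);
    ++c;
  }
  return List::create(_["n_cycles"] = c,
                      _["cycle_of"] = IntegerVector(cyc.begin(), cyc.end()) + 1,
                      _["verts"] = verts,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                      _["w1"] = NumericVector(cw1.begin(), cw1.end()),
                      _["w2"] = NumericVector(cw2.begin(), cw2.end()));
}

// Maximum zero-sum partition of a zero-sum multiset of nonzero integers,
// solved by the O*(3^n) fixed-parameter dynamic program: for every zero-sum
// subset S, f[S] is the maximum number of zero-sum parts partitioning S,
// obtained by enumerating the part T that contains the smallest element of
// S.  Enumerating (T, S \ T) over all S visits each disjoint pair once,
// i.e. the 3^n states of the Held-Karp style table.  A witness partition is
// recovered by backtracking on the stored choices.
// [[Rcpp::export]]
List mzsp_dp_cpp(NumericVector values) {
  const int n = values.size();
  if (n > 25) stop("dynamic program limited to 25 elements");
  if (n == 0)
    return List::create(_["p"] = 0, _["assignment"] = IntegerVector(0));
  std::vector<int64_t> val(n);
  for (int i = 0; i < n; ++i) val[i] = (int64_t) values[i];
  const uint32_t full = (1u << n) - 1u;
  std::vector<int64_t> sum(full + 1, 0);
  for (uint32_t S = 1; S <= full; ++S) {
    uint32_t low = S & (~S + 1u);
    int idx = 0; while (!((low >> idx) & 1u)) ++idx;
    sum[S] = sum[S & (S - 1u)] + val[idx];
  }
  if (sum[full] != 0) stop("input multiset must sum to zero");
  std::vector<int> f(full + 1, -1);
  std::vector<uint32_t> choice(full + 1, 0);
  f[0] = 0;
  for (uint32_t S = 1; S <= full; ++S) {
    if (sum[S] != 0) continue;       // only zero-sum states are reachable
    uint32_t low = S & (~S + 1u);
    uint32_t rest = S ^ low;
    int best = -1; uint32_t bch = 0;
    // subsets T of S containing the lowest element: T = sub | low
    uint32_t sub = rest;
    while (true) {
      uint32_t T = sub | low;
      if (sum[T] == 0 && f[S ^ T] >= 0 && 1 + f[S ^ T] > best) {
        best = 1 + f[S ^ T];
        bch = T;
      }
      if (sub == 0) break;
      sub = (sub - 1u) & rest;
    }
    f[S] = best;                     // >= 1: S itself is a zero-sum part
    choice[S] = bch;
  }
  IntegerVector assign(n, NA_INTEGER);
  uint32_t S = full;
  int part = 0;
  while (S) {
    ++part;
    uint32_t T = choice[S];
    for (int i = 0; i < n; ++i)
      if ((T >> i) & 1u) assign[i] = part;
    S ^= T;
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["p"] = f[full], _["assignment"] = assign);
}
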