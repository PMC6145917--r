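#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Pairwise identity under semi-global alignment with free terminal gaps.
//
// Scoring: match +1, mismatch -1, gap -2; free terminal gaps contribute no
// columns. Identity = matches / alignment columns over the aligned core
// (internal gaps and mismatches count as columns). Among co-optimal
// alignments the objective is fully deterministic: maximize score, then
// matches, then minimize columns. 'N' never matches anything.
//
// Two end-gap modes:
//  fit (default): terminal gaps are free only on the reference side; the
//    query spans the alignment end to end (its terminal gaps are scored and
//    counted). Symmetry is obtained by evaluating both orientations and
//    keeping the lexicographically better triple. This is the glocal
//    placement alignment: a contained sequence scores identity 1, while two
//    divergent sequences are forced into a (possibly negative-scoring)
//    spanning alignment instead of a trivially perfect micro-overlap.
//  overlap: terminal gaps free on both sequences (suffix-prefix overlaps
//    allowed). Degenerates on divergent pairs -- the best score is often a
//    tiny exact overlap -- which is why it is not the default.

struct Tri {
  int s;  // alignment score
  int m;  // match columns
  int c;  // total columns in the aligned core
};

static inline bool tri_better(const Tri &a, const Tri &b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.m != b.m) return a.m > b.m;
  return a.c < b.c;
}

static inline bool is_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// Fit alignment: query q spans; reference r has free terminal gaps.
// Returns the best triple over the last DP row.
static Tri fit_core(const std::string &q, const std::string &r) {
  const int n = (int)q.size();
  const int m = (int)r.size();
  std::vector<Tri> prev((size_t)m + 1), cur((size_t)m + 1);
  for (int j = 0; j <= m; ++j) prev[(size_t)j] = {0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    cur[0] = {-2 * i, 0, i};  // consuming the query against gaps is scored
    const char qi = q[(size_t)(i - 1)];
    for (int j = 1; j <= m; ++j) {
      const bool match = is_match(qi, r[(size_t)(j - 1)]);
      Tri d = {prev[(size_t)(j - 1)].s + (match ? 1 : -1),
               prev[(size_t)(j - 1)].m + (match ? 1 : 0),
               prev[(size_t)(j - 1)].c + 1};
      Tri u = {prev[(size_t)j].s - 2, prev[(size_t)j].m,
               prev[(size_t)j].c + 1};
      Tri l = {cur[(size_t)(j - 1)].s - 2, cur[(size_t)(j - 1)].m,
               cur[(size_t)(j - 1)].c + 1};
      Tri v = d;
      if (tri_better(u, v)) v = u;
      if (tri_better(l, v)) v = l;
      cur[(size_t)j] = v;
    }
    std::swap(prev, cur);
  }
  Tri best = prev[0];
  for (int j = 1; j <= m; ++j)
    if (tri_better(prev[(size_t)j], best)) best = prev[(size_t)j];
  return best;
}

// Overlap alignment: terminal gaps free on both sequences; best over the
// last row and last column (the empty alignment {0,0,0} included).
static Tri overlap_core(const std::string &a, const std::string &b) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  std::vector<Tri> prev((size_t)m + 1), cur((size_t)m + 1);
  for (int j = 0; j <= m; ++j) prev[(size_t)j] = {0, 0, 0};
  Tri best = {0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    cur[0] = {0, 0, 0};
    const char ai = a[(size_t)(i - 1)];
    for (int j = 1; j <= m; ++j) {
      const bool match = is_match(ai, b[(size_t)(j - 1)]);
      Tri d = {prev[(size_t)(j - 1)].s + (match ? 1 : -1),
               prev[(size_t)(j - 1)].m + (match ? 1 : 0),
               prev[(size_t)(j - 1)].c + 1};
      Tri u = {prev[(size_t)j].s - 2, prev[(size_t)j].m,
               prev[(size_t)j].c + 1};
      Tri l = {cur[(size_t)(j - 1)].s - 2, cur[(size_t)(j - 1)].m,
               cur[(size_t)(j - 1)].c + 1};
      Tri v = d;
      if (tri_better(u, v)) v = u;
      if (tri_better(l, v)) v = l;
      cur[(size_t)j] = v;
    }
    if (tri_better(cur[(size_t)m], best)) best = cur[(size_t)m];
    std::swap(prev, cur);
  }
  for (int j = 0; j <= m; ++j)
    if (tri_better(prev[(size_t)j], best)) best = prev[(size_t)j];
  return best;
}

static double identity_core(const std::string &a, const std::string &b,
                            bool fit) {
  if (a.empty() || b.empty())
    stop("pairwise identity requires non-empty sequences");
  Tri best;
  if (fit) {
    best = fit_core(a, b);
    Tri rev = fit_core(b, a);
    if (tri_better(rev, best)) best = rev;
  } else {
    best = overlap_core(a, b);
  }
  if (best.c == 0) return 0.0;
  double id = (double)best.m / (double)best.c;
  return id > 0.0 ? id : 0.0;
}

// [[Rcpp::export(name = ".identity_pair_cpp")]]
double identity_pair_cpp(std::string a, std::string b, bool fit) {
  return identity_core(a, b, fit);
}

// [[Rcpp::export(name = ".identity_many_cpp")]]
NumericVector identity_many_cpp(std::string query, CharacterVector refs,
                                bool fit) {
  const int k = refs.size();
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    std::string r = as<std::string>(refs[i]);
    out[i] = identity_core(query, r, fit);
  }
  return out;
}
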