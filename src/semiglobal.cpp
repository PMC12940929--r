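#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Unit-cost edit distance with free end gaps for the longer sequence:
// the shorter sequence (query) must align end-to-end inside the longer
// (target); leading/trailing target bases are not penalized. 'N' matches
// nothing (mismatch against every base, including another N).

static inline bool match_base(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

static int sg_cost_one(const std::string& a, const std::string& b) {
  const std::string& q = a.size() <= b.size() ? a : b;
  const std::string& t = a.size() <= b.size() ? b : a;
  const int n = (int)q.size(), m = (int)t.size();
  std::vector<int> col(n + 1), prev(n + 1);
  for (int i = 0; i <= n; ++i) prev[i] = i;  // gaps in target before start
  int best = prev[n];
  for (int j = 1; j <= m; ++j) {
    col[0] = 0;  // free leading target overhang
    const char tc = t[j - 1];
    for (int i = 1; i <= n; ++i) {
      int d = prev[i - 1] + (match_base(q[i - 1], tc) ? 0 : 1);
      int del = prev[i] + 1;   // consume target base (gap in query)
      int ins = col[i - 1] + 1; // consume query base (gap in target)
      col[i] = std::min(d, std::min(del, ins));
    }
    best = std::min(best, col[n]);  // free trailing target overhang
    std::swap(col, prev);
  }
  return best;
}

// [[Rcpp::export(name = ".sg_cost")]]
int sg_cost_cpp(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("empty sequence");
  return sg_cost_one(a, b);
}

// Cost matrix reads x refs (no orientation handling; caller supplies
// reverse complements separately).
// [[Rcpp::export(name = ".sg_cost_matrix")]]
IntegerMatrix sg_cost_matrix_cpp(CharacterVector reads, CharacterVector refs) {
  const int nr = reads.size(), nc = refs.size();
  std::vector<std::string> rs(nr), fs(nc);
  for (int i = 0; i < nr; ++i) {
    rs[i] = as<std::string>(reads[i]);
    if (rs[i].empty()) stop("empty read sequence at index %d", i + 1);
  }
  for (int j = 0; j < nc; ++j) {
    fs[j] = as<std::string>(refs[j]);
    if (fs[j].empty()) stop("empty reference sequence at index %d", j + 1);
  }
  IntegerMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = sg_cost_one(rs[i], fs[j]);
  return out;
}
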