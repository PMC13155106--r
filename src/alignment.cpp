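#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global alignment maximizing (matches, aligned pairs) lexicographically.
// Scoring per site: match = BIG + 1, mismatch = 1, gap = 0, BIG = m + n + 1,
// so the number of matches strictly dominates and, among match-optimal
// alignments, the one aligning the most residue pairs (shortest alignment)
// is selected. Identity = matches / alignment length, with
// alignment length = m + n - pairs. End gaps cost like internal gaps.
static void nw_core(const std::string& a, const std::string& b,
                    int& matches, int& pairs) {
  const int m = (int)a.size(), n = (int)b.size();
  const long long BIG = (long long)m + n + 1;
  std::vector<long long> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = 0;
    const char ai = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      long long best = prev[j - 1] + (ai == b[j - 1] ? BIG + 1 : 1);
      if (prev[j] > best) best = prev[j];
      if (cur[j - 1] > best) best = cur[j - 1];
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  long long s = prev[n];
  matches = (int)(s / BIG);
  pairs = (int)(s % BIG);
}

static double identity_of(const std::string& a, const std::string& b,
                          int& matches, int& alen) {
  int pairs;
  nw_core(a, b, matches, pairs);
  alen = (int)a.size() + (int)b.size() - pairs;
  return (double)matches / (double)alen;
}

// [[Rcpp::export(name = ".nw_stats")]]
NumericVector nw_stats(std::string a, std::string b) {
  int matches, alen;
  double id = identity_of(a, b, matches, alen);
  return NumericVector::create(_["matches"] = matches,
                               _["align_length"] = alen,
                               _["identity"] = id);
}

// [[Rcpp::export(name = ".identity_vec")]]
NumericVector identity_vec(std::string query, CharacterVector refs) {
  int nr = refs.size();
  NumericVector out(nr);
  for (int k = 0; k < nr; ++k) {
    std::string r = as<std::string>(refs[k]);
    int matches, alen;
    out[k] = identity_of(query, r, matches, alen);
  }
  return out;
}

// Best match over a pool; ties broken by first (lowest) index. Pairs whose
// length ratio min/max falls below len_ratio_min are skipped (their identity
// cannot reach min/max anyway when len_ratio_min >= threshold of interest).
// [[Rcpp::export(name = ".identity_best")]]
NumericVector identity_best(std::string query, CharacterVector refs,
                            double len_ratio_min) {
  int nr = refs.size();
  double best = -1.0;
  int best_idx = 0; // 0 = none evaluated
  int qn = (int)query.size();
  for (int k = 0; k < nr; ++k) {
    std::string r = as<std::string>(refs[k]);
    int rn = (int)r.size();
    if (len_ratio_min > 0) {
      double lo = (double)std::min(qn, rn), hi = (double)std::max(qn, rn);
      if (hi > 0 && lo / hi < len_ratio_min) continue;
    }
    int matches, alen;
    double id = identity_of(query, r, matches, alen);
    if (id > best) { best = id; best_idx = k + 1; }
  }
  return NumericVector::create(_["index"] = (double)best_idx,
                               _["identity"] = best < 0 ? NA_REAL : best);
}

// First ref with identity >= threshold (or > threshold when strict),
// in pool order; 0 when none qualifies.
// [[Rcpp::export(name = ".identity_first")]]
int identity_first(std::string query, CharacterVector refs, double threshold,
                   bool strict, double len_ratio_min) {
  int nr = refs.size();
  int qn = (int)query.size();
  for (int k = 0; k < nr; ++k) {
    std::string r = as<std::string>(refs[k]);
    int rn = (int)r.size();
    if (len_ratio_min > 0) {
      double lo = (double)std::min(qn, rn), hi = (double)std::max(qn, rn);
      if (hi > 0 && lo / hi < len_ratio_min) continue;
    }
    int matches, alen;
    double id = identity_of(query, r, matches, alen);
    if (strict ? (id > threshold) : (id >= threshold)) return k + 1;
  }
  return 0;
}
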