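#include <Rcpp.h>
using namespace Rcpp;

// Longest common substring by dynamic programming over two byte strings.
// Returns (length, start_a, start_b), 1-based starts; ties broken by the
// smallest end (hence start) in a, then in b. Characters match only if
// identical bytes, so IUPAC ambiguity codes match themselves only.
// [[Rcpp::export(name = ".lcs_dp")]]
IntegerVector lcs_dp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), curr(m + 1, 0);
  int best = 0, end_a = 0, end_b = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      curr[j] = (ai == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (curr[j] > best) { best = curr[j]; end_a = i; end_b = j; }
    }
    std::swap(prev, curr);
  }
  return IntegerVector::create(best, end_a - best + 1, end_b - best + 1);
}

// Length-only variant used inside the permutation null, where positions are
// irrelevant and the call count is large.
// [[Rcpp::export(name = ".lcs_len")]]
int lcs_len(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), curr(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      curr[j] = (ai == b[j - 1]) ? prev[j - 1] + 1 : 0;
      if (curr[j] > best) best = curr[j];
    }
    std::swap(prev, curr);
  }
  return best;
}
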