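// Unit-cost Levenshtein distance over integer token sequences (two-row DP).
#include <Rcpp.h>
using namespace Rcpp;

//' @noRd
// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(const IntegerVector& a, const IntegerVector& b) {
  int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min({prev[j] + 1, cur[j - 1] + 1, sub});
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
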