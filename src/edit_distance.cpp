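#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

// Exact global Levenshtein distance with two rolling rows. Unit costs for
// substitution, insertion and deletion.
static int lev_dp(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    const char ca = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (ca == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
Rcpp::IntegerVector levenshtein_cpp(Rcpp::CharacterVector a,
                                    Rcpp::CharacterVector b) {
  if (a.size() != b.size())
    Rcpp::stop("string vectors must have equal length");
  Rcpp::IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    std::string sa = Rcpp::as<std::string>(a[i]);
    std::string sb = Rcpp::as<std::string>(b[i]);
    out[i] = (sa == sb) ? 0 : lev_dp(sa, sb);
  }
  return out;
}
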