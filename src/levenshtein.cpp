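#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Plain Levenshtein distance (unit-cost substitution, insertion,
// deletion) between integer-encoded label sequences. Encoding to
// integers happens in R so labels of any width compare correctly.

static int lev_one(const int *a, int na, const int *b, int nb,
                   std::vector<int> &prev, std::vector<int> &cur) {
  if (na == 0) return nb;
  if (nb == 0) return na;
  for (int j = 0; j <= nb; ++j) prev[j] = j;
  for (int i = 1; i <= na; ++i) {
    cur[0] = i;
    for (int j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".lev_pairs")]]
Rcpp::IntegerVector lev_pairs(Rcpp::List a, Rcpp::List b) {
  const R_xlen_t n = a.size();
  if (b.size() != n) Rcpp::stop("a and b must have equal length");
  Rcpp::IntegerVector out(n);
  std::vector<int> prev(64), cur(64);
  for (R_xlen_t i = 0; i < n; ++i) {
    Rcpp::IntegerVector ai = a[i], bi = b[i];
    size_t need = (size_t)std::max(ai.size(), bi.size()) + 1;
    if (prev.size() < need) { prev.resize(need); cur.resize(need); }
    out[i] = lev_one(INTEGER(ai), ai.size(), INTEGER(bi), bi.size(),
                     prev, cur);
  }
  return out;
}
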