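#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty and a fixed
// traceback tie-break: diagonal, then up (gap in query), then left (gap in
// reference). The deterministic traceback is part of the projection
// contract: the same pair of promoters always yields the same site
// projection.

// [[Rcpp::export]]
List nw_align_cpp(std::string ref, std::string query,
                  double match, double mismatch, double gap) {
  const int n = ref.size(), m = query.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;
      double best = S(i - 1, j - 1) + s;          // diagonal
      double up = S(i - 1, j) + gap;              // gap in query
      double left = S(i, j - 1) + gap;            // gap in ref
      if (up > best) best = up;
      if (left > best) best = left;
      S(i, j) = best;
    }
  }
  // traceback, preferring diagonal, then up, then left on ties
  std::string ar, aq;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;
      if (std::abs(S(i, j) - (S(i - 1, j - 1) + s)) < eps) {
        ar.push_back(ref[i - 1]); aq.push_back(query[j - 1]);
        --i; --j; continue;
      }
    }
    if (i > 0 && std::abs(S(i, j) - (S(i - 1, j) + gap)) < eps) {
      ar.push_back(ref[i - 1]); aq.push_back('-'); --i; continue;
    }
    ar.push_back('-'); aq.push_back(query[j - 1]); --j;
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(aq.begin(), aq.end());
  return List::create(_["aligned_ref"] = ar, _["aligned_query"] = aq,
                      _["score"] = S(n, m));
}
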