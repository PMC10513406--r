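#include <Rcpp.h>
#include <string>
#include <vector>

// Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
// gap penalty -1. Identity = matches / alignment length, taken from the
// traceback alignment with deterministic tie-breaking (diagonal preferred
// over up over left), so results are reproducible across platforms.

// [[Rcpp::export(name = ".nw_identity")]]
double nw_identity(const std::string& a, const std::string& b) {
  const int n = (int)a.size();
  const int m = (int)b.size();
  if (n == 0 || m == 0) Rcpp::stop("sequences must be non-empty");

  std::vector<int> prev(m + 1), cur(m + 1);
  // traceback: 0 = diag, 1 = up (gap in b), 2 = left (gap in a)
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) { prev[j] = -j; tb[j] = 2; }
  tb[0] = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = -i;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sdiag = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int sup = prev[j] - 1;
      int sleft = cur[j - 1] - 1;
      int best = sdiag; unsigned char dir = 0;
      if (sup > best) { best = sup; dir = 1; }
      if (sleft > best) { best = sleft; dir = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = dir;
    }
    std::swap(prev, cur);
  }

  int i = n, j = m;
  long matches = 0, length = 0;
  while (i > 0 || j > 0) {
    unsigned char dir = tb[(size_t)i * (m + 1) + j];
    ++length;
    if (dir == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      --i; --j;
    } else if (dir == 1) {
      --i;
    } else {
      --j;
    }
  }
  return (double)matches / (double)length;
}
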