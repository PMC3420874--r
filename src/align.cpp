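#include <Rcpp.h>
using namespace Rcpp;

// Global alignment maximising the number of identical aligned positions
// (match +1, mismatch 0, gap 0). Traceback prefers diagonal over up over
// left so substitutions are paired as mismatch columns rather than split
// into gap pairs, making the identity denominator deterministic.
//
// Returns: matches, aligned columns excluding terminal overhangs, and the
// number of residues of the shorter sequence falling inside that region.
// [[Rcpp::export(name = ".nw_stats")]]
IntegerVector nw_stats(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // DP score matrix, row-major (n+1) x (m+1)
  std::vector<int> S((n + 1) * (m + 1), 0);
  for (int i = 1; i <= n; ++i) {
    const int *prev = &S[(i - 1) * (m + 1)];
    int *cur = &S[i * (m + 1)];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int u = prev[j];
      int l = cur[j - 1];
      int best = d >= u ? d : u;
      if (l > best) best = l;
      cur[j] = best;
    }
  }

  // traceback, collecting column flags from the end
  std::vector<unsigned char> colA, colB, colM;  // reversed order
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = S[i * (m + 1) + j];
    if (i > 0 && j > 0) {
      int d = S[(i - 1) * (m + 1) + (j - 1)] + (a[i - 1] == b[j - 1] ? 1 : 0);
      if (d == cur) {
        colA.push_back(1); colB.push_back(1);
        colM.push_back(a[i - 1] == b[j - 1] ? 1 : 0);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && S[(i - 1) * (m + 1) + j] == cur) {
      colA.push_back(1); colB.push_back(0); colM.push_back(0);
      --i;
      continue;
    }
    colA.push_back(0); colB.push_back(1); colM.push_back(0);
    --j;
  }
  const int L = colA.size();

  // trim terminal overhangs: region where both sequences have started and
  // neither has finished
  int firstA = -1, lastA = -1, firstB = -1, lastB = -1;
  for (int k = 0; k < L; ++k) {
    int c = L - 1 - k;  // colA is reversed
    if (colA[c]) { if (firstA < 0) firstA = k; lastA = k; }
    if (colB[c]) { if (firstB < 0) firstB = k; lastB = k; }
  }
  int start = std::max(firstA, firstB);
  int end = std::min(lastA, lastB);

  int matches = 0, cols = 0, shorter_res = 0;
  const bool a_shorter = n <= m;
  for (int k = start; k <= end; ++k) {
    int c = L - 1 - k;
    ++cols;
    if (colM[c]) ++matches;
    if (a_shorter ? colA[c] : colB[c]) ++shorter_res;
  }
  if (end < start) { cols = 0; matches = 0; shorter_res = 0; }

  return IntegerVector::create(matches, cols, shorter_res);
}
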