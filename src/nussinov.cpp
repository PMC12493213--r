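#include <Rcpp.h>
using namespace Rcpp;

// Maximum base-pairing secondary structure (nested, minimum hairpin loop of
// 3 unpaired bases) with a deterministic leftmost-pairing traceback.
// Bases are passed as integer codes: A=0, C=1, G=2, T/U=3. `forbidden`
// marks positions forced to stay single-stranded (used to generate
// deterministic suboptimal topologies). Returns the 1-based partner index
// per position, 0 for unpaired.

static inline bool can_pair(int a, int b, bool wobble) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return true; // A-T/U
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return true; // C-G
  if (wobble && ((a == 2 && b == 3) || (a == 3 && b == 2))) return true;
  return false;
}

// [[Rcpp::export(name = ".nussinov_pairing")]]
IntegerVector nussinov_pairing(IntegerVector codes, LogicalVector forbidden,
                               bool wobble = false, int min_loop = 3) {
  const int n = codes.size();
  IntegerVector partner(n, 0);
  if (n < 2) return partner;
  std::vector<int> code(n);
  std::vector<char> forb(n);
  for (int i = 0; i < n; ++i) { code[i] = codes[i]; forb[i] = forbidden[i]; }
  // dp[i][j] = max pairs on [i, j], 0-based, stored in a flat vector
  std::vector<int> dp((size_t)n * n, 0);
  auto at = [&](int i, int j) -> int& { return dp[(size_t)i * n + j]; };
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = at(i, j - 1); // j unpaired
      if (!forb[j]) {
        const int cj = code[j];
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (forb[k] || !can_pair(code[k], cj, wobble)) continue;
          int v = 1 + (k > i ? at(i, k - 1) : 0) + at(k + 1, j - 1);
          if (v > best) best = v;
        }
      }
      at(i, j) = best;
    }
  }
  // iterative traceback, leftmost pairing partner wins ties
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (at(i, j) == at(i, j - 1)) { // prefer j unpaired on ties
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (forbidden[k] || forbidden[j]) continue;
      if (!can_pair(codes[k], codes[j], wobble)) continue;
      int v = 1 + (k > i ? at(i, k - 1) : 0) + at(k + 1, j - 1);
      if (v == at(i, j)) {
        partner[k] = j + 1;
        partner[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return partner;
}
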