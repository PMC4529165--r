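#include <Rcpp.h>
#include <stack>
using namespace Rcpp;

// Base-pair maximization (Nussinov) over DNA/RNA with Watson-Crick + wobble
// pairs and a minimum hairpin loop. Dynamic program is O(n^3); traceback is
// deterministic (pairing (i,j) preferred over bifurcation at the lowest k).

static inline bool can_pair(char a, char b) {
  switch (a) {
  case 'A': return b == 'T' || b == 'U';
  case 'T': case 'U': return b == 'A' || b == 'G';
  case 'G': return b == 'C' || b == 'T' || b == 'U';
  case 'C': return b == 'G';
  default: return false; // ambiguity codes never pair
  }
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  int n = seq.size();
  for (int i = 0; i < n; ++i) seq[i] = std::toupper(seq[i]);
  if (n == 0) stop("empty sequence");
  std::vector<int> dp((size_t)n * n, 0);
  auto D = [&](int i, int j) -> int& { return dp[(size_t)i * n + j]; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = D(i, j - 1); // j unpaired
      if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
        int v = 1 + (i + 1 <= j - 1 ? D(i + 1, j - 1) : 0);
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) { // j paired with k
        if (can_pair(seq[k], seq[j]) && j - k > min_loop) {
          int v = (k > i ? D(i, k - 1) : 0) + 1 +
                  (k + 1 <= j - 1 ? D(k + 1, j - 1) : 0);
          if (v > best) best = v;
        }
      }
      D(i, j) = best;
    }
  }

  std::string db(n, '.');
  std::vector<int> pair(n, 0); // 1-based partner, 0 = unpaired
  std::stack<std::pair<int, int> > st;
  st.push(std::make_pair(0, n - 1));
  while (!st.empty()) {
    int i = st.top().first, j = st.top().second;
    st.pop();
    if (i >= j || j - i <= min_loop) continue;
    if (D(i, j) == D(i, j - 1)) { st.push(std::make_pair(i, j - 1)); continue; }
    if (can_pair(seq[i], seq[j]) &&
        D(i, j) == 1 + (i + 1 <= j - 1 ? D(i + 1, j - 1) : 0)) {
      db[i] = '('; db[j] = ')';
      pair[i] = j + 1; pair[j] = i + 1;
      st.push(std::make_pair(i + 1, j - 1));
      continue;
    }
    bool done = false;
    for (int k = i + 1; k < j && !done; ++k) {
      if (can_pair(seq[k], seq[j]) && j - k > min_loop) {
        int v = (k > i ? D(i, k - 1) : 0) + 1 +
                (k + 1 <= j - 1 ? D(k + 1, j - 1) : 0);
        if (v == D(i, j)) {
          db[k] = '('; db[j] = ')';
          pair[k] = j + 1; pair[j] = k + 1;
          if (k > i) st.push(std::make_pair(i, k - 1));
          st.push(std::make_pair(k + 1, j - 1));
          done = true;
        }
      }
    }
    if (!done) stop("traceback failure"); // unreachable by construction
  }

  int np = n >= 2 ? D(0, n - 1) : 0;
  return List::create(_["structure"] = db,
                      _["n_pairs"] = np,
                      _["pairing"] = IntegerVector(pair.begin(), pair.end()));
}
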