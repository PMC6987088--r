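#include <Rcpp.h>
#include <deque>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Constrained randomization of a co-barcoding dataset: the multiset of
// feature tokens is shuffled and dealt into barcode groups visited in
// random order; a token duplicating a feature already in the current group
// is pushed onto a carry-forward queue that is consumed first by the next
// group (so abundant features are not lost to rejection). If the deal gets
// stuck (a tail group cannot be completed without a duplicate) the whole
// deal restarts with a fresh shuffle. Uses R's RNG so set.seed() governs.

static inline int runif_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static bool fill_once(const std::vector<int>& tokens,
                      const IntegerVector& sizes,
                      const std::vector<int>& offsets,
                      std::vector<int>& flat,
                      std::vector<int>& shuffled,
                      std::vector<int>& order_g) {
  const int n_tok = (int)tokens.size();
  const int ng = sizes.size();
  shuffled = tokens;
  for (int i = n_tok - 1; i > 0; --i)
    std::swap(shuffled[i], shuffled[runif_index(i + 1)]);
  order_g.resize(ng);
  for (int i = 0; i < ng; ++i) order_g[i] = i;
  for (int i = ng - 1; i > 0; --i)
    std::swap(order_g[i], order_g[runif_index(i + 1)]);

  std::deque<int> carry;
  std::vector<int> rejected;
  int ptr = 0;
  for (int gi = 0; gi < ng; ++gi) {
    const int g = order_g[gi];
    const int k = sizes[g];
    int* cur = flat.data() + offsets[g];
    int filled = 0;
    rejected.clear();
    while (filled < k) {
      int cand;
      if (!carry.empty()) {
        cand = carry.front();
        carry.pop_front();
      } else if (ptr < n_tok) {
        cand = shuffled[ptr++];
      } else {
        return false;  // stuck: restart with a fresh shuffle
      }
      bool dup = false;
      for (int j = 0; j < filled; ++j)
        if (cur[j] == cand) { dup = true; break; }
      if (dup) rejected.push_back(cand);
      else cur[filled++] = cand;
    }
    for (int j = (int)rejected.size() - 1; j >= 0; --j)
      carry.push_front(rejected[j]);
  }
  return carry.empty() && ptr == n_tok;
}

// one randomization: returns a (total tokens) x 2 matrix of
// (group id, feature id), both 1-based
// [[Rcpp::export]]
IntegerMatrix mc_assign_once(IntegerVector tokens, IntegerVector sizes,
                             int max_restarts) {
  const int n_tok = tokens.size();
  std::vector<int> tok(n_tok);
  for (int i = 0; i < n_tok; ++i) tok[i] = tokens[i];
  const int ng = sizes.size();
  std::vector<int> offsets(ng + 1, 0);
  for (int g = 0; g < ng; ++g) offsets[g + 1] = offsets[g] + sizes[g];
  if (offsets[ng] != n_tok) stop("token count does not match group sizes");
  std::vector<int> flat(n_tok), shuffled, order_g;
  int restarts = 0;
  while (!fill_once(tok, sizes, offsets, flat, shuffled, order_g)) {
    if (++restarts > max_restarts) stop("randomization restart cap exceeded");
  }
  IntegerMatrix out(n_tok, 2);
  int row = 0;
  for (int g = 0; g < ng; ++g)
    for (int j = 0; j < sizes[g]; ++j, ++row) {
      out(row, 0) = g + 1;
      out(row, 1) = flat[offsets[g] + j];
    }
  out.attr("restarts") = restarts;
  return out;
}

// n_rand randomizations, accumulating per-pair counts
// [[Rcpp::export]]
List mc_pair_sums(IntegerVector tokens, IntegerVector sizes, int n_rand,
                  int max_restarts) {
  const int n_tok = tokens.size();
  std::vector<int> tok(n_tok);
  int nf = 0;
  for (int i = 0; i < n_tok; ++i) {
    tok[i] = tokens[i];
    if (tokens[i] > nf) nf = tokens[i];
  }
  const int ng = sizes.size();
  std::vector<int> offsets(ng + 1, 0);
  for (int g = 0; g < ng; ++g) offsets[g + 1] = offsets[g] + sizes[g];
  if (offsets[ng] != n_tok) stop("token count does not match group sizes");

  std::vector<int> flat(n_tok), shuffled, order_g;
  std::unordered_map<long long, double> acc;
  long long total_restarts = 0;
  for (int r = 0; r < n_rand; ++r) {
    int restarts = 0;
    while (!fill_once(tok, sizes, offsets, flat, shuffled, order_g)) {
      if (++restarts > max_restarts)
        stop("randomization restart cap exceeded");
    }
    total_restarts += restarts;
    for (int g = 0; g < ng; ++g) {
      const int k = sizes[g];
      if (k < 2) continue;
      const int* cur = flat.data() + offsets[g];
      for (int a = 0; a < k; ++a)
        for (int b = a + 1; b < k; ++b) {
          int i = cur[a], j = cur[b];
          if (i > j) std::swap(i, j);
          acc[(long long)i * (nf + 1) + j] += 1.0;
        }
    }
    if ((r & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  const int m = (int)acc.size();
  IntegerVector ai(m), bj(m);
  NumericVector s(m);
  int p = 0;
  for (const auto& kv : acc) {
    ai[p] = (int)(kv.first / (nf + 1));
    bj[p] = (int)(kv.first % (nf + 1));
    s[p] = kv.second;
    ++p;
  }
  return List::create(_["i"] = ai, _["j"] = bj, _["sum"] = s,
                      _["restarts"] = (double)total_restarts);
}
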