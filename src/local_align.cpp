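// k-mer-seeded banded Smith-Waterman local alignment (linear gap
// penalty). Seeds restrict the DP band to the diagonals supported by
// exact k-mer matches, so consensus sequences without any shared k-mer
// are rejected in O(n). Path start coordinates are propagated through
// the DP instead of a traceback matrix.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// [[Rcpp::export(name = ".sw_seeded")]]
IntegerVector sw_seeded(std::string query, std::string target,
                        int k = 11, int band = 50,
                        int match = 2, int mismatch = -3, int gap = -4) {
  const int n = query.size(), m = target.size();
  IntegerVector out = IntegerVector::create(
    _["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
    _["t_start"] = 0, _["t_end"] = 0);
  if (n < k || m < k) return out;

  std::vector<int> q(n), t(m);
  for (int i = 0; i < n; ++i) q[i] = base_code(query[i]);
  for (int j = 0; j < m; ++j) t[j] = base_code(target[j]);

  // hash target k-mers (2-bit encoding; windows containing N skipped)
  std::unordered_map<uint64_t, std::vector<int>> index;
  {
    uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
    int run = 0;
    for (int j = 0; j < m; ++j) {
      if (t[j] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)t[j]) & mask;
      if (++run >= k) index[key].push_back(j - k + 1);
    }
  }
  // scan query k-mers, collect matched diagonals d = j - i
  int dmin = m + n, dmax = -(m + n);
  {
    uint64_t key = 0, mask = (1ULL << (2 * k)) - 1;
    int run = 0;
    for (int i = 0; i < n; ++i) {
      if (q[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)q[i]) & mask;
      if (++run >= k) {
        auto it = index.find(key);
        if (it != index.end()) {
          int qi = i - k + 1;
          for (int tj : it->second) {
            int d = tj - qi;
            if (d < dmin) dmin = d;
            if (d > dmax) dmax = d;
          }
        }
      }
    }
  }
  if (dmin > dmax) return out;   // no seed: no hit
  dmin -= band; dmax += band;

  // banded DP; origin (path start) carried along with the score
  std::vector<int> prev(m + 1, 0), curr(m + 1, 0);
  std::vector<int> pq0(m + 1, 0), pt0(m + 1, 0);
  std::vector<int> cq0(m + 1, 0), ct0(m + 1, 0);
  int best = 0, bi = 0, bj = 0, bq0 = 0, bt0 = 0;
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(1, i + dmin);
    int hi = std::min(m, i + dmax);
    if (lo > hi) continue;
    if (lo - 1 >= 0) { curr[lo - 1] = 0; }
    for (int j = lo; j <= hi; ++j) {
      int sub = (q[i - 1] >= 0 && q[i - 1] == t[j - 1]) ? match : mismatch;
      int diag = prev[j - 1] + sub;
      int up = prev[j] + gap;     // gap in target (consume query)
      int left = curr[j - 1] + gap;
      int s = diag;
      int oq = pq0[j - 1], ot = pt0[j - 1];
      if (prev[j - 1] == 0) { oq = i - 1; ot = j - 1; }
      if (up > s) { s = up; oq = pq0[j]; ot = pt0[j]; }
      if (left > s) { s = left; oq = cq0[j - 1]; ot = ct0[j - 1]; }
      if (s <= 0) { s = 0; oq = i; ot = j; }
      curr[j] = s; cq0[j] = oq; ct0[j] = ot;
      if (s > best) { best = s; bi = i; bj = j; bq0 = oq; bt0 = ot; }
    }
    if (hi + 1 <= m) { curr[hi + 1] = 0; }
    std::swap(prev, curr);
    std::swap(pq0, cq0);
    std::swap(pt0, ct0);
  }
  out["score"] = best;
  out["q_start"] = bq0;   // 0-based
  out["q_end"] = bi;      // half-open
  out["t_start"] = bt0;
  out["t_end"] = bj;
  return out;
}
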