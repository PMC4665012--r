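#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Triplet code over A/C/G/T: 0..63; -1 when any base is not ACGT (excluded
// from scoring).
static inline int base2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// DUST-style low-complexity masking.
//
// An interval [i, j] (0-based, inclusive, 4 <= length <= window) is flagged
// when its triplet coincidence score
//     S = sum_t c_t (c_t - 1) / 2  /  (l - 1)
// exceeds `threshold` (= level / 10), where c_t counts each of the 64
// ACGT-triplets inside the interval and l = number of scoreable (N-free)
// triplets; intervals with l < 2 are never flagged.  The mask is the union of
// all flagged intervals; flagged bases are replaced by N.
//
// For a fixed start i the flagged j's need not be marked one by one: all
// intervals share the start, so the union over j is [i, max flagged j].
// [[Rcpp::export(name = ".pf_dust_mask")]]
std::string pf_dust_mask(std::string seq, double threshold, int window) {
  const int n = (int)seq.size();
  if (n < 4) return seq;
  std::vector<int> tri(std::max(0, n - 2));
  for (int i = 0; i + 2 < n; ++i) {
    int a = base2(seq[i]), b = base2(seq[i + 1]), c = base2(seq[i + 2]);
    tri[i] = (a < 0 || b < 0 || c < 0) ? -1 : ((a << 4) | (b << 2) | c);
  }
  std::vector<int> mark(n + 1, 0); // difference array
  std::vector<int> cnt(64, 0);
  for (int i = 0; i < n - 3; ++i) {
    std::fill(cnt.begin(), cnt.end(), 0);
    long long pairs = 0;
    int l = 0;
    int jmax = -1;
    const int hi = std::min(n - 1, i + window - 1);
    for (int j = i + 2; j <= hi; ++j) {
      // adding triplet starting at j-2 completes bases [i, j]
      int t = tri[j - 2];
      if (t >= 0) {
        pairs += cnt[t];
        cnt[t]++;
        l++;
      }
      if (j - i + 1 >= 4 && l >= 2) {
        double score = (double)pairs / (double)(l - 1);
        if (score > threshold + 1e-12) jmax = j;
      }
    }
    if (jmax >= 0) { mark[i] += 1; mark[jmax + 1] -= 1; }
  }
  int acc = 0;
  for (int i = 0; i < n; ++i) {
    acc += mark[i];
    if (acc > 0) seq[i] = 'N';
  }
  return seq;
}
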