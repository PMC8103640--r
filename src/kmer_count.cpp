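#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding: A=0, C=1, G=2, T=3; anything else breaks the current window.
static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Canonical k-mer multiplicity histogram over a set of reads.
// Returns a two-column integer matrix (multiplicity, n_distinct_kmers),
// multiplicities ascending. k must be odd and <= 31 so a k-mer fits in
// 62 bits and no k-mer is its own reverse complement.
// [[Rcpp::export]]
IntegerMatrix kmer_histogram_cpp(CharacterVector reads, int k) {
  if (k < 3 || k > 31) stop("k must be in [3, 31]");
  if (k % 2 == 0) stop("k must be odd (even k makes canonical form ambiguous)");

  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int rc_shift = 2 * (k - 1);

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    if (reads[r] == NA_STRING) continue;
    const char *s = CHAR(reads[r]);
    uint64_t fwd = 0, rev = 0;
    int run = 0;  // valid bases accumulated in the current window
    for (const char *p = s; *p; ++p) {
      int b = encode_base(*p);
      if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - b) << rc_shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }

  std::unordered_map<uint32_t, uint32_t> hist;
  for (const auto &kv : counts) ++hist[kv.second];
  std::vector<std::pair<uint32_t, uint32_t>> rows(hist.begin(), hist.end());
  std::sort(rows.begin(), rows.end());

  IntegerMatrix out(rows.size(), 2);
  for (size_t i = 0; i < rows.size(); ++i) {
    out(i, 0) = (int)rows[i].first;
    out(i, 1) = (int)rows[i].second;
  }
  colnames(out) = CharacterVector::create("multiplicity", "count");
  return out;
}
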