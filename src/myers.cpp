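#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Bit-parallel semi-global edit distance (Myers 1999, block extension after
// Hyyro 2003). The full pattern must align; it may start and end anywhere in
// the text. Returns the minimal distance and the 0-based text position where
// the best alignment ends. Symbols are 0..3 (A,C,G,T); 4 (N) never matches.

// [[Rcpp::export]]
List myers_search_cpp(IntegerVector pattern, IntegerVector text) {
  const int m = pattern.size();
  const int n = text.size();
  if (m < 1 || n < 1) stop("empty pattern or text");

  const int W = 64;
  const int B = (m + W - 1) / W;

  // per-block match masks for A,C,G,T
  std::vector<uint64_t> Peq(B * 4, 0ULL);
  for (int i = 0; i < m; ++i) {
    int c = pattern[i];
    if (c >= 0 && c < 4)
      Peq[(i / W) * 4 + c] |= (1ULL << (i % W));
  }

  std::vector<uint64_t> Pv(B, ~0ULL), Mv(B, 0ULL);
  const uint64_t last_bit = 1ULL << ((m - 1) % W);
  const int last_blk = B - 1;

  int score = m, best = m + n + 1, best_end = -1;

  for (int j = 0; j < n; ++j) {
    const int c = text[j];
    int hin = 0;  // D[0][j] - D[0][j-1] = 0: free start anywhere
    for (int b = 0; b < B; ++b) {
      const uint64_t hbit = (b == last_blk) ? last_bit : (1ULL << (W - 1));
      uint64_t Eq = (c >= 0 && c < 4) ? Peq[b * 4 + c] : 0ULL;
      const uint64_t Xv = Eq | Mv[b];
      if (hin < 0) Eq |= 1ULL;
      const uint64_t Xh = (((Eq & Pv[b]) + Pv[b]) ^ Pv[b]) | Eq;
      uint64_t Ph = Mv[b] | ~(Xh | Pv[b]);
      uint64_t Mh = Pv[b] & Xh;

      int hout = 0;
      if (Ph & hbit) hout = 1;
      else if (Mh & hbit) hout = -1;
      if (b == last_blk) score += hout;

      Ph <<= 1;
      Mh <<= 1;
      if (hin < 0) Mh |= 1ULL;
      else if (hin > 0) Ph |= 1ULL;

      Pv[b] = Mh | ~(Xv | Ph);
      Mv[b] = Ph & Xv;
      hin = hout;
    }
    if (score < best) { best = score; best_end = j; }
  }
  return List::create(_["distance"] = best, _["end"] = best_end);
}
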