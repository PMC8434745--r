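#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; anything else (N, ambiguity) is -1 and breaks a k-mer.
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Canonical (strand-folded) k-mer histogram over a set of reads.
// Returns depth -> number of distinct canonical k-mers seen at that depth.
// k <= 31 so a k-mer fits in one uint64.
// [[Rcpp::export(name = ".kmer_histogram_cpp")]]
List kmer_histogram_cpp(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char *s = CHAR(STRING_ELT(reads, r));
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // bases accumulated since last invalid char
    for (const char *p = s; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }
  // histogram of depths
  std::unordered_map<uint32_t, uint32_t> hist;
  for (auto &kv : counts) ++hist[kv.second];
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (auto &kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  IntegerVector depth(depths.size()), count(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    depth[i] = (int)depths[i];
    count[i] = (int)hist[depths[i]];
  }
  return List::create(_["depth"] = depth, _["count"] = count);
}

// Windowed symmetric-DUST low-complexity masking.
// Score of a window = 10 * sum_t c_t(c_t-1)/2 / (l - 1), where c_t are
// triplet multiplicities among the l valid (ACGT-only) triplets in the
// window. Windows scoring above `threshold` are masked; the union of masked
// windows is returned as merged 0-based half-open intervals.
// [[Rcpp::export(name = ".dust_intervals_cpp")]]
IntegerMatrix dust_intervals_cpp(std::string seq, int window, double threshold) {
  int n = (int)seq.size();
  if (window < 3) stop("window must be >= 3");
  std::vector<int> trip(n > 2 ? n - 2 : 0, -1); // triplet code at each start
  for (int i = 0; i + 2 < n; ++i) {
    int a = base_code(seq[i]), b = base_code(seq[i + 1]), c = base_code(seq[i + 2]);
    if (a >= 0 && b >= 0 && c >= 0) trip[i] = (a << 4) | (b << 2) | c;
  }
  int w = std::min(window, n);
  int nt = w - 2; // triplets per full window
  if (nt < 1 || n < 3) return IntegerMatrix(0, 2);

  std::vector<int> cnt(64, 0);
  long long pairsum = 0; // sum c(c-1)/2
  int lvalid = 0;
  std::vector<char> masked(n, 0);

  // initialise first window [0, w)
  for (int i = 0; i < nt; ++i) {
    int t = trip[i];
    if (t >= 0) { pairsum += cnt[t]; ++cnt[t]; ++lvalid; }
  }
  int last_start = n - w;
  for (int s = 0; ; ++s) {
    if (lvalid >= 2) {
      double score = 10.0 * (double)pairsum / (double)(lvalid - 1);
      if (score > threshold)
        for (int i = s; i < s + w; ++i) masked[i] = 1;
    }
    if (s == last_start) break;
    int tout = trip[s];
    if (tout >= 0) { --cnt[tout]; pairsum -= cnt[tout]; --lvalid; }
    int tin = trip[s + nt];
    if (tin >= 0) { pairsum += cnt[tin]; ++cnt[tin]; ++lvalid; }
  }

  // merge masked runs into intervals
  std::vector<int> starts, ends;
  int i = 0;
  while (i < n) {
    if (masked[i]) {
      int j = i;
      while (j < n && masked[j]) ++j;
      starts.push_back(i);
      ends.push_back(j);
      i = j;
    } else ++i;
  }
  IntegerMatrix out((int)starts.size(), 2);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = ends[r];
  }
  return out;
}

// Uniform random DNA string generator (seeded from R's RNG).
// [[Rcpp::export(name = ".random_dna_cpp")]]
CharacterVector random_dna_cpp(IntegerVector lengths) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(lengths.size());
  for (R_xlen_t i = 0; i < lengths.size(); ++i) {
    int n = lengths[i];
    std::string s(n, 'A');
    for (int j = 0; j < n; ++j) s[j] = bases[(int)(unif_rand() * 4) & 3];
    out[i] = s;
  }
  return out;
}
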