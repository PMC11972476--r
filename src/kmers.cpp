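// Per-position genomic k-mer occurrence counts h_k(i), exact and with a
// bounded number of mismatches. Counting is strand-aware: the occurrence
// table is built from the forward k-mers of every fragment and of every
// fragment's reverse complement, so a k-mer unique on the forward strand but
// repeated on the reverse strand is not reported as unique.
//
// k <= 31 (2-bit packed in a 64-bit word). Positions whose window contains N
// are reported as NA (poison) and never enter the occurrence table.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Flat open-addressing hash table (linear probing) for 2-bit packed k-mers.
// Keys are < 2^62; the all-ones word marks an empty slot. Sized at load
// factor <= 0.4, lookups stay at a couple of probes, which matters because
// mismatch counting performs ~2000 Hamming-ball lookups per position.
struct KmerTable {
  std::vector<uint64_t> keys;
  std::vector<int32_t> vals;
  uint64_t mask;

  explicit KmerTable(size_t expected) {
    size_t cap = 64;
    while (cap < expected * 5 / 2 + 16) cap <<= 1;
    keys.assign(cap, ~0ULL);
    vals.assign(cap, 0);
    mask = cap - 1;
  }
  static inline uint64_t hash(uint64_t x) {
    x += 0x9e3779b97f4a7c15ULL;
    x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
    x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
    return x ^ (x >> 31);
  }
  inline void add(uint64_t key) {
    uint64_t i = hash(key) & mask;
    for (;;) {
      if (keys[i] == key) { ++vals[i]; return; }
      if (keys[i] == ~0ULL) { keys[i] = key; vals[i] = 1; return; }
      i = (i + 1) & mask;
    }
  }
  inline int32_t get(uint64_t key) const {
    uint64_t i = hash(key) & mask;
    for (;;) {
      if (keys[i] == key) return vals[i];
      if (keys[i] == ~0ULL) return 0;
      i = (i + 1) & mask;
    }
  }
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N or anything else poisons the k-mer
  }
}

// Append all valid (N-free) forward k-mers of seq into the occurrence table.
static void tally_kmers(const std::string& seq, int k, KmerTable& tab) {
  const int n = (int) seq.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t word = 0;
  int valid = 0; // number of consecutive valid bases ending here
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; word = 0; continue; }
    word = ((word << 2) | (uint64_t) c) & mask;
    if (++valid >= k) tab.add(word);
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

// Sum of table counts over the Hamming ball of radius m around `word`.
static inline long ball_count(uint64_t word, int k, int m,
                              const KmerTable& tab) {
  long total = 0;
  auto look = [&](uint64_t w) { total += tab.get(w); };
  look(word);
  if (m >= 1) {
    for (int p = 0; p < k; ++p) {
      const int shift = 2 * p;
      const uint64_t cur = (word >> shift) & 3ULL;
      for (uint64_t b = 0; b < 4; ++b) {
        if (b == cur) continue;
        const uint64_t w1 = (word & ~(3ULL << shift)) | (b << shift);
        look(w1);
        if (m >= 2) {
          for (int q = p + 1; q < k; ++q) {
            const int shift2 = 2 * q;
            const uint64_t cur2 = (w1 >> shift2) & 3ULL;
            for (uint64_t b2 = 0; b2 < 4; ++b2) {
              if (b2 == cur2) continue;
              look((w1 & ~(3ULL << shift2)) | (b2 << shift2));
            }
          }
        }
      }
    }
  }
  return total;
}

// [[Rcpp::export]]
List cpp_kmer_counts(CharacterVector fragments, int k, int m) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  if (m < 0 || m >= k) stop("mismatch allowance must satisfy 0 <= m < k");
  const int nf = fragments.size();

  std::vector<std::string> seqs(nf);
  for (int f = 0; f < nf; ++f) seqs[f] = as<std::string>(fragments[f]);

  size_t total_len = 0;
  for (const auto& s : seqs) total_len += s.size();
  KmerTable tab(2 * total_len + 16);
  for (const auto& s : seqs) {
    tally_kmers(s, k, tab);
    tally_kmers(revcomp_str(s), k, tab);
  }

  const uint64_t mask = ((1ULL << (2 * k)) - 1);
  List out(nf);
  for (int f = 0; f < nf; ++f) {
    const std::string& s = seqs[f];
    const int n = (int) s.size();
    const int npos = n - k + 1;
    if (npos <= 0) { out[f] = IntegerVector(0); continue; }
    IntegerVector counts(npos, NA_INTEGER);
    uint64_t word = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; word = 0; continue; }
      word = ((word << 2) | (uint64_t) c) & mask;
      ++valid;
      if (valid >= k) {
        long v = (m == 0) ? ball_count(word, k, 0, tab)
                          : ball_count(word, k, m, tab);
        counts[i - k + 1] = (int) v;
      }
    }
    out[f] = counts;
  }
  out.attr("names") = fragments.attr("names");
  return out;
}

// [[Rcpp::export]]
String cpp_revcomp(std::string seq) {
  return revcomp_str(seq);
}
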