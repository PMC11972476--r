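// Seed-and-extend local aligner. Exact word seeding on the forward subject
// strand (query is additionally searched reverse-complemented), banded
// gapped extension with affine gap costs and x-drop termination. Gap of
// length L costs open + ext * L (blastn convention). Raw scores only; the
// Karlin-Altschul conversion to bits / E-values lives in R.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <climits>
#include <cstdint>

using namespace Rcpp;

// Direct-address word index: for word size w <= 12, bucket offsets over the
// full 4^w word space (counting sort), subject positions packed fragment<<32
// | position. Two linear passes, no per-bucket allocation.
struct WordIndex {
  int w;
  std::vector<uint32_t> offsets;      // 4^w + 1
  std::vector<uint64_t> positions;    // packed (frag, pos), bucket-grouped

  WordIndex(const std::vector<std::string>& frags, int word_size) : w(word_size) {
    const size_t nwords = 1ULL << (2 * w);
    const uint64_t mask = nwords - 1;
    offsets.assign(nwords + 1, 0);
    size_t total = 0;
    for (const auto& s : frags) {
      uint64_t word = 0; int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c;
        switch (s[i]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
        }
        if (c < 0) { valid = 0; word = 0; continue; }
        word = ((word << 2) | (uint64_t) c) & mask;
        if (++valid >= w) { ++offsets[word + 1]; ++total; }
      }
    }
    for (size_t i = 1; i <= nwords; ++i) offsets[i] += offsets[i - 1];
    positions.resize(total);
    std::vector<uint32_t> cursor(offsets.begin(), offsets.end() - 1);
    for (size_t f = 0; f < frags.size(); ++f) {
      const std::string& s = frags[f];
      uint64_t word = 0; int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int c;
        switch (s[i]) {
        case 'A': c = 0; break; case 'C': c = 1; break;
        case 'G': c = 2; break; case 'T': c = 3; break;
        default: c = -1;
        }
        if (c < 0) { valid = 0; word = 0; continue; }
        word = ((word << 2) | (uint64_t) c) & mask;
        if (++valid >= w)
          positions[cursor[word]++] =
            ((uint64_t) f << 32) | (uint64_t) (i - w + 1);
      }
    }
  }
};

static const int NEG = INT_MIN / 4;

static inline int bcode(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string rc(const std::string& s) {
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

struct ScoreParams {
  int match, mismatch, open, ext, word, band, xdrop;
};

// N never scores as a match.
static inline int sub_score(char a, char b, const ScoreParams& p) {
  if (a == 'N' || b == 'N') return p.mismatch;
  return (a == b) ? p.match : p.mismatch;
}

struct ExtRes {
  int score;   // best achievable score; 0 if the extension is empty
  int ci, cj;  // consumed characters of query/subject at the best cell
};

// Banded affine x-drop extension. Cells are (i, j) = numbers of consumed
// characters, starting from a virtual origin of score 0 at the anchor
// boundary, so the extension may open with a gap (a gap directly adjacent
// to the seed word is representable). The character consumed at step i is
// q[qa + dir*(i-1)]; analogously for the subject.
static ExtRes band_extend(const std::string& q, const std::string& s,
                          int qa, int sa, int dir, const ScoreParams& p) {
  const int B = p.band, W = 2 * B + 1;
  int Nq, Ns; // available characters in this direction
  if (dir > 0) { Nq = (int) q.size() - qa; Ns = (int) s.size() - sa; }
  else         { Nq = qa + 1;              Ns = sa + 1; }
  if (Nq <= 0 || Ns <= 0) return {0, 0, 0};

  std::vector<int> H(W, NEG), Iq(W, NEG), Is(W, NEG);
  std::vector<int> Hn(W), Iqn(W), Isn(W);

  auto qc = [&](int i) { return q[qa + dir * (i - 1)]; };
  auto sc = [&](int j) { return s[sa + dir * (j - 1)]; };

  int best = 0, bci = 0, bcj = 0;

  // row i = 0: virtual origin plus leading gaps in the query
  H[B] = 0;
  for (int u = B + 1; u < W; ++u) {
    int tj = u - B;
    if (tj > Ns) break;
    int from_open = (H[u - 1] > NEG / 2) ? H[u - 1] - p.open - p.ext : NEG;
    int from_ext  = (Iq[u - 1] > NEG / 2) ? Iq[u - 1] - p.ext : NEG;
    Iq[u] = std::max(from_open, from_ext);
    H[u] = Iq[u];
  }

  for (int i = 1; i <= Nq; ++i) {
    int rowmax = NEG;
    std::fill(Hn.begin(), Hn.end(), NEG);
    std::fill(Iqn.begin(), Iqn.end(), NEG);
    std::fill(Isn.begin(), Isn.end(), NEG);
    for (int u = 0; u < W; ++u) {
      int tj = i + (u - B);
      if (tj < 0 || tj > Ns) continue;
      // vertical: from (i-1, tj), offset u+1 in the previous row
      if (u + 1 < W) {
        int a = (H[u + 1] > NEG / 2) ? H[u + 1] - p.open - p.ext : NEG;
        int b = (Is[u + 1] > NEG / 2) ? Is[u + 1] - p.ext : NEG;
        Isn[u] = std::max(a, b);
      }
      // diagonal: from (i-1, tj-1), same offset u
      int M = NEG;
      if (tj >= 1 && H[u] > NEG / 2) M = H[u] + sub_score(qc(i), sc(tj), p);
      // horizontal: from (i, tj-1), offset u-1 in the current row
      if (u >= 1) {
        int a = (Hn[u - 1] > NEG / 2) ? Hn[u - 1] - p.open - p.ext : NEG;
        int b = (Iqn[u - 1] > NEG / 2) ? Iqn[u - 1] - p.ext : NEG;
        Iqn[u] = std::max(a, b);
      }
      int h = std::max(M, std::max(Isn[u], Iqn[u]));
      Hn[u] = h;
      if (h > rowmax) rowmax = h;
      if (h > best) { best = h; bci = i; bcj = tj; }
    }
    H.swap(Hn); Iq.swap(Iqn); Is.swap(Isn);
    if (rowmax < best - p.xdrop) break;
  }

  return {best, bci, bcj};
}

struct Frag {
  int qs, qe, ss, se; // half-open, query forward coords
  int sfrag;          // 0-based subject fragment
  char strand;
  int raw;
};

// seeds-and-extends one query orientation against one indexed subject
static void scan_orientation(const std::string& q, int orig_qlen, char strand,
                             const std::vector<std::string>& frags,
                             const WordIndex& idx,
                             const ScoreParams& p, std::vector<Frag>& out) {
  const int w = p.word;
  const int qlen = (int) q.size();
  if (qlen < w) return;
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  // rectangles already produced, per subject fragment (this orientation)
  std::unordered_map<int, std::vector<std::array<int, 4>>> rects;

  uint64_t word = 0;
  int valid = 0;
  for (int i = 0; i < qlen; ++i) {
    int c = bcode(q[i]);
    if (c < 0) { valid = 0; word = 0; continue; }
    word = ((word << 2) | (uint64_t) c) & mask;
    if (++valid < w) continue;
    const int qp = i - w + 1;
    for (uint32_t e = idx.offsets[word]; e < idx.offsets[word + 1]; ++e) {
      const uint64_t packed = idx.positions[e];
      const int f = (int) (packed >> 32), sp = (int) (packed & 0xffffffffULL);
      bool covered = false;
      auto rit = rects.find(f);
      if (rit != rects.end()) {
        for (const auto& r : rit->second) {
          if (qp >= r[0] && qp < r[1] && sp >= r[2] && sp < r[3]) {
            covered = true; break;
          }
        }
      }
      if (covered) continue;
      const std::string& s = frags[f];
      ExtRes right = band_extend(q, s, qp, sp, +1, p);
      ExtRes left = {0, 0, 0};
      if (qp > 0 && sp > 0) left = band_extend(q, s, qp - 1, sp - 1, -1, p);
      int raw = right.score + left.score;
      if (raw <= 0) continue;
      int qs = qp - left.ci;
      int ss = sp - left.cj;
      int qe = qp + right.ci;
      int se = sp + right.cj;
      rects[f].push_back({qs, qe, ss, se});
      Frag fr;
      fr.sfrag = f; fr.strand = strand; fr.raw = raw;
      fr.ss = ss; fr.se = se;
      if (strand == '+') { fr.qs = qs; fr.qe = qe; }
      else { fr.qs = orig_qlen - qe; fr.qe = orig_qlen - qs; }
      out.push_back(fr);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_multi(CharacterVector queries, CharacterVector subject,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int word_size, int band, int x_drop) {
  if (word_size < 4 || word_size > 12) stop("word size must be in [4, 12]");
  ScoreParams p{match, mismatch, gap_open, gap_extend, word_size, band, x_drop};

  const int nf = subject.size();
  std::vector<std::string> frags(nf);
  for (int f = 0; f < nf; ++f) frags[f] = as<std::string>(subject[f]);

  // word index over the forward strand of every subject fragment
  WordIndex idx(frags, word_size);

  std::vector<int> o_query, o_qs, o_qe, o_sf, o_ss, o_se, o_raw;
  std::vector<std::string> o_strand;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string q = as<std::string>(queries[qi]);
    const int qlen = (int) q.size();
    if (qlen < word_size)
      stop("query %d is shorter than the seed word size", qi + 1);
    std::vector<Frag> found;
    scan_orientation(q, qlen, '+', frags, idx, p, found);
    scan_orientation(rc(q), qlen, '-', frags, idx, p, found);
    // drop exact duplicates and fragments contained in a higher-scoring one
    std::vector<char> keep(found.size(), 1);
    for (size_t a = 0; a < found.size(); ++a) {
      if (!keep[a]) continue;
      for (size_t b = 0; b < found.size(); ++b) {
        if (a == b || !keep[b]) continue;
        const Frag& A = found[a];
        const Frag& B = found[b];
        if (A.sfrag != B.sfrag || A.strand != B.strand) continue;
        bool contained = B.qs >= A.qs && B.qe <= A.qe &&
                         B.ss >= A.ss && B.se <= A.se;
        if (contained && (B.raw < A.raw || (B.raw == A.raw && b > a)))
          keep[b] = 0;
      }
    }
    for (size_t a = 0; a < found.size(); ++a) {
      if (!keep[a]) continue;
      const Frag& F = found[a];
      o_query.push_back(qi + 1);
      o_qs.push_back(F.qs); o_qe.push_back(F.qe);
      o_sf.push_back(F.sfrag + 1);
      o_ss.push_back(F.ss); o_se.push_back(F.se);
      o_strand.push_back(std::string(1, F.strand));
      o_raw.push_back(F.raw);
    }
  }

  return DataFrame::create(
    _["query"] = o_query, _["qstart"] = o_qs, _["qend"] = o_qe,
    _["sfrag"] = o_sf, _["sstart"] = o_ss, _["send"] = o_se,
    _["strand"] = o_strand, _["raw"] = o_raw,
    _["stringsAsFactors"] = false);
}

// Exact full-matrix Smith-Waterman local score with affine gaps
// (gap of length L costs open + ext*L). Quadratic reference scorer.
// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, int match, int mismatch,
                 int gap_open, int gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) return 0;
  std::vector<int> H(m + 1, 0), F(m + 1, NEG); // F: vertical gap state per column
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Hdiag = 0; // H[i-1][j-1]
    int E = NEG;   // horizontal gap state, runs along the row
    for (int j = 1; j <= m; ++j) {
      int Hup = H[j]; // H[i-1][j]
      E = std::max(H[j - 1] - gap_open - gap_extend,
                   (E > NEG / 2 ? E - gap_extend : NEG));
      F[j] = std::max(Hup - gap_open - gap_extend,
                      (F[j] > NEG / 2 ? F[j] - gap_extend : NEG));
      int sc = (a[i - 1] == 'N' || b[j - 1] == 'N')
                 ? mismatch
                 : (a[i - 1] == b[j - 1] ? match : mismatch);
      int h = std::max(0, Hdiag + sc);
      h = std::max(h, std::max(E, F[j]));
      Hdiag = Hup;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_sw_score_many(std::string a, CharacterVector bs, int match,
                                int mismatch, int gap_open, int gap_extend) {
  IntegerVector out(bs.size());
  for (int i = 0; i < bs.size(); ++i)
    out[i] = cpp_sw_score(a, as<std::string>(bs[i]), match, mismatch,
                          gap_open, gap_extend);
  return out;
}
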