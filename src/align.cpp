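// Core ungapped alignment kernels: seeded all-to-all read similarity search,
// the exhaustive all-diagonal oracle, best-scoring overlap hits for pairwise
// similarity statistics, junction-tag scanning, and contig consensus helpers.
//
// All routines operate on substitution-only alignments (no gaps): a candidate
// alignment between two reads is a diagonal, i.e. a fixed offset, and a hit is
// a contiguous segment on a diagonal satisfying the identity/length criteria.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// base codes: A=0 C=1 G=2 T=3, anything else (incl. N)=4, never matching
static inline uint8_t enc_base(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<uint8_t> enc_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc_base(s[i]);
  return v;
}

static std::vector<uint8_t> rc_seq(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t b = v[v.size() - 1 - i];
    r[i] = (b < 4) ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  return r;
}

struct SegHit {
  int len;      // segment length (columns)
  int start;    // 0-based start within the diagonal overlap
  int matches;  // matching columns
  bool found;
};

// Longest segment of the 0/1 match vector m[0..L) whose identity (in percent,
// scaled by 100: id100 units of 0.01%) is >= the threshold and whose length is
// >= min_len.  Among maximal-length qualifying segments the one with the
// smallest start is returned.  Uses integer prefix weights:
//   match weight 10000 - id100, mismatch weight -id100,
// so sum(w) >= 0  <=>  matches * 10000 >= id100 * len.
static SegHit longest_qualifying(const uint8_t *m, int L, long long id100,
                                 int min_len) {
  SegHit out{0, 0, 0, false};
  if (L < min_len) return out;
  static std::vector<long long> P;
  P.resize(L + 1);
  P[0] = 0;
  const long long wm = 10000 - id100, wx = -id100;
  for (int i = 0; i < L; ++i) P[i + 1] = P[i] + (m[i] ? wm : wx);
  // maximum width j - i with P[j] >= P[i]: monotone stack of prefix minima
  static std::vector<int> st;
  st.clear();
  st.reserve(L + 1);
  for (int i = 0; i <= L; ++i)
    if (st.empty() || P[i] < P[st.back()]) st.push_back(i);
  int best = 0;
  for (int j = L; j >= 1; --j) {
    while (!st.empty() && P[st.back()] <= P[j]) {
      best = std::max(best, j - st.back());
      st.pop_back();
    }
    if (st.empty()) break;
  }
  if (best < min_len) return out;
  // smallest start achieving the maximal width
  for (int i = 0; i + best <= L; ++i) {
    if (P[i + best] - P[i] >= 0) {
      int matches = 0;
      for (int k = i; k < i + best; ++k) matches += m[k];
      out.len = best;
      out.start = i;
      out.matches = matches;
      out.found = true;
      return out;
    }
  }
  return out;  // unreachable
}

// Evaluate one diagonal of A (fwd) vs B (already oriented).  diag = posA - posB.
// Returns the longest qualifying segment, with 'start' converted to the A
// coordinate of the segment start.
static SegHit eval_diagonal(const std::vector<uint8_t> &A,
                            const std::vector<uint8_t> &B, int diag,
                            long long id100, int min_len) {
  const int la = (int)A.size(), lb = (int)B.size();
  const int ia0 = std::max(0, diag);
  const int ia1 = std::min(la, lb + diag);  // exclusive
  SegHit out{0, 0, 0, false};
  const int L = ia1 - ia0;
  if (L < min_len) return out;
  static std::vector<uint8_t> m;
  m.resize(L);
  for (int t = 0; t < L; ++t) {
    const uint8_t a = A[ia0 + t], b = B[ia0 + t - diag];
    m[t] = (a < 4 && a == b) ? 1 : 0;
  }
  SegHit h = longest_qualifying(m.data(), L, id100, min_len);
  if (h.found) h.start += ia0;  // A coordinate
  return h;
}

struct PairBest {
  int b;
  int orient;  // 0 same, 1 reverse
  int diag;
  SegHit hit;
};

// Shared output assembly -------------------------------------------------
static DataFrame hits_to_df(const std::vector<int> &va, const std::vector<PairBest> &vh,
                            const std::vector<int> &lens) {
  const size_t n = vh.size();
  IntegerVector a(n), b(n), hlen(n), sa(n), ea(n), sb(n), eb(n);
  NumericVector ident(n);
  CharacterVector orient(n);
  for (size_t i = 0; i < n; ++i) {
    const PairBest &p = vh[i];
    a[i] = va[i] + 1;
    b[i] = p.b + 1;
    hlen[i] = p.hit.len;
    ident[i] = 100.0 * p.hit.matches / p.hit.len;
    // A span (1-based inclusive)
    sa[i] = p.hit.start + 1;
    ea[i] = p.hit.start + p.hit.len;
    // B span on the original (forward) B sequence
    int bs = p.hit.start - p.diag;          // 0-based start on oriented B
    int be = bs + p.hit.len;                // exclusive
    if (p.orient == 0) {
      sb[i] = bs + 1;
      eb[i] = be;
    } else {
      int lb = lens[p.b];
      sb[i] = lb - be + 1;
      eb[i] = lb - bs;
    }
    orient[i] = (p.orient == 0) ? "same" : "reverse";
  }
  return DataFrame::create(_["a"] = a, _["b"] = b, _["orientation"] = orient,
                           _["identity"] = ident, _["hit_length"] = hlen,
                           _["start_a"] = sa, _["end_a"] = ea,
                           _["start_b"] = sb, _["end_b"] = eb,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = "cpp_find_hits")]]
DataFrame cpp_find_hits(CharacterVector seqs, double min_identity,
                        int min_overlap, int seed_len) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t>> fwd(n), rev(n);
  std::vector<int> lens(n);
  int maxlen = 0;
  for (int i = 0; i < n; ++i) {
    fwd[i] = enc_seq(as<std::string>(seqs[i]));
    rev[i] = rc_seq(fwd[i]);
    lens[i] = (int)fwd[i].size();
    maxlen = std::max(maxlen, lens[i]);
  }
  const long long id100 = (long long)std::llround(min_identity * 100.0);

  if (seed_len < 1 || seed_len > 15) stop("seed_len must be in [1, 15]");
  if (maxlen >= 8000) stop("reads longer than 8 kb are not supported");

  // k-mer index over forward and reverse-complement sequences
  typedef std::unordered_map<uint32_t, std::vector<uint64_t>> Index;
  Index idx_f, idx_r;
  const uint32_t mask = (seed_len == 16) ? 0xFFFFFFFFu
                                         : ((1u << (2 * seed_len)) - 1u);
  auto index_seq = [&](Index &idx, const std::vector<uint8_t> &s, int read) {
    uint32_t key = 0;
    int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      if (s[p] > 3) {
        run = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | s[p]) & mask;
      if (++run >= seed_len)
        idx[key].push_back(((uint64_t)read << 16) | (uint64_t)(p - seed_len + 1));
    }
  };
  for (int i = 0; i < n; ++i) {
    index_seq(idx_f, fwd[i], i);
    index_seq(idx_r, rev[i], i);
  }

  std::vector<int> out_a;
  std::vector<PairBest> out_h;
  const int DOFF = 8192;  // diagonal offset for packing

  std::vector<uint64_t> cand;
  for (int a = 0; a < n; ++a) {
    cand.clear();
    // enumerate this read's k-mers once
    const std::vector<uint8_t> &s = fwd[a];
    uint32_t key = 0;
    int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      if (s[p] > 3) {
        run = 0;
        key = 0;
        continue;
      }
      key = ((key << 2) | s[p]) & mask;
      if (++run < seed_len) continue;
      const int pa = p - seed_len + 1;
      Index::const_iterator it = idx_f.find(key);
      if (it != idx_f.end()) {
        for (uint64_t pk : it->second) {
          const int b = (int)(pk >> 16);
          if (b <= a) continue;
          const int pb = (int)(pk & 0xFFFF);
          const uint64_t d = (uint64_t)(pa - pb + DOFF);
          cand.push_back(((uint64_t)b << 16) | (d << 1));
        }
      }
      it = idx_r.find(key);
      if (it != idx_r.end()) {
        for (uint64_t pk : it->second) {
          const int b = (int)(pk >> 16);
          if (b <= a) continue;
          const int pb = (int)(pk & 0xFFFF);
          const uint64_t d = (uint64_t)(pa - pb + DOFF);
          cand.push_back(((uint64_t)b << 16) | (d << 1) | 1u);
        }
      }
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    // evaluate candidates; keep the best hit per (b, orientation):
    // maximal length, ties broken by the smallest diagonal
    int cur_b = -1, cur_o = -1;
    PairBest best{};
    bool have = false;
    auto flush = [&]() {
      if (have) {
        out_a.push_back(a);
        out_h.push_back(best);
      }
      have = false;
    };
    for (uint64_t c : cand) {
      const int b = (int)(c >> 16);
      const int o = (int)(c & 1u);
      const int diag = (int)((c >> 1) & 0x7FFFu) - DOFF;
      if (b != cur_b || o != cur_o) {
        flush();
        cur_b = b;
        cur_o = o;
      }
      const std::vector<uint8_t> &B = (o == 0) ? fwd[b] : rev[b];
      SegHit h = eval_diagonal(fwd[a], B, diag, id100, min_overlap);
      if (!h.found) continue;
      if (!have || h.len > best.hit.len) {
        best.b = b;
        best.orient = o;
        best.diag = diag;
        best.hit = h;
        have = true;
      }
    }
    flush();
  }
  return hits_to_df(out_a, out_h, lens);
}

// Exhaustive all-pairs, all-diagonals search at the same thresholds.  Written
// as a naive enumeration (longest-first scan over every segment of every
// diagonal) so it is an independent reference for the seeded implementation.
// [[Rcpp::export(name = "cpp_all_hits_bruteforce")]]
DataFrame cpp_all_hits_bruteforce(CharacterVector seqs, double min_identity,
                                  int min_overlap) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t>> fwd(n), rev(n);
  std::vector<int> lens(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = enc_seq(as<std::string>(seqs[i]));
    rev[i] = rc_seq(fwd[i]);
    lens[i] = (int)fwd[i].size();
  }
  const long long id100 = (long long)std::llround(min_identity * 100.0);
  std::vector<int> out_a;
  std::vector<PairBest> out_h;
  std::vector<int> cum;  // prefix match counts for one diagonal

  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      for (int o = 0; o < 2; ++o) {
        const std::vector<uint8_t> &A = fwd[a];
        const std::vector<uint8_t> &B = (o == 0) ? fwd[b] : rev[b];
        const int la = (int)A.size(), lb = (int)B.size();
        PairBest best{};
        bool have = false;
        for (int diag = -(lb - min_overlap); diag <= la - min_overlap; ++diag) {
          const int i0 = std::max(0, diag);
          const int i1 = std::min(la, lb + diag);
          const int L = i1 - i0;
          if (L < min_overlap) continue;
          cum.assign(L + 1, 0);
          for (int t = 0; t < L; ++t) {
            const uint8_t x = A[i0 + t], y = B[i0 + t - diag];
            cum[t + 1] = cum[t] + ((x < 4 && x == y) ? 1 : 0);
          }
          // longest qualifying segment, smallest start
          SegHit h{0, 0, 0, false};
          for (int len = L; len >= min_overlap && !h.found; --len) {
            for (int s0 = 0; s0 + len <= L; ++s0) {
              const int mt = cum[s0 + len] - cum[s0];
              if ((long long)mt * 10000 >= id100 * (long long)len) {
                h.len = len;
                h.start = i0 + s0;
                h.matches = mt;
                h.found = true;
                break;
              }
            }
          }
          if (h.found && (!have || h.len > best.hit.len)) {
            best.b = b;
            best.orient = o;
            best.diag = diag;
            best.hit = h;
            have = true;
          }
        }
        if (have) {
          out_a.push_back(a);
          out_h.push_back(best);
        }
      }
    }
  }
  return hits_to_df(out_a, out_h, lens);
}

// Best-scoring ungapped segment for given read pairs (both orientations, all
// diagonals; Kadane per diagonal, match +5 / mismatch -4 by default).  Used
// for the average pairwise similarity statistic, where hits below a length
// cutoff are discarded and similarities are rescaled by the maximal overlap
// implied by the hit's diagonal.
// [[Rcpp::export(name = "cpp_best_overlap_hits")]]
DataFrame cpp_best_overlap_hits(CharacterVector seqs, IntegerVector ia,
                                IntegerVector ib, int match_score,
                                int mismatch_penalty, int min_len) {
  const int n = seqs.size();
  std::vector<std::vector<uint8_t>> fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = enc_seq(as<std::string>(seqs[i]));
    rev[i] = rc_seq(fwd[i]);
  }
  const int np = ia.size();
  NumericVector ident(np), adj(np);
  IntegerVector hlen(np), ovl(np);
  LogicalVector found(np);
  for (int p = 0; p < np; ++p) {
    const int a = ia[p] - 1, b = ib[p] - 1;
    long best_score = -1;
    int best_len = 0, best_matches = 0, best_ovl = 0;
    for (int o = 0; o < 2; ++o) {
      const std::vector<uint8_t> &A = fwd[a];
      const std::vector<uint8_t> &B = (o == 0) ? fwd[b] : rev[b];
      const int la = (int)A.size(), lb = (int)B.size();
      for (int diag = -(lb - 1); diag <= la - 1; ++diag) {
        const int i0 = std::max(0, diag);
        const int i1 = std::min(la, lb + diag);
        const int L = i1 - i0;
        if (L < min_len) continue;
        long run = 0;
        int rlen = 0, rmat = 0;
        for (int t = 0; t < L; ++t) {
          const uint8_t x = A[i0 + t], y = B[i0 + t - diag];
          const bool mt = (x < 4 && x == y);
          const long w = mt ? (long)match_score : -(long)mismatch_penalty;
          if (run + w < w) {  // restart
            run = w;
            rlen = 1;
            rmat = mt ? 1 : 0;
          } else {
            run += w;
            rlen += 1;
            rmat += mt ? 1 : 0;
          }
          if (rlen >= min_len && run > best_score) {
            best_score = run;
            best_len = rlen;
            best_matches = rmat;
            best_ovl = L;
          }
        }
      }
    }
    if (best_score >= 0 && best_len >= min_len) {
      found[p] = true;
      hlen[p] = best_len;
      ovl[p] = best_ovl;
      ident[p] = 100.0 * best_matches / best_len;
      adj[p] = ident[p] * (double)best_len / (double)best_ovl;
    } else {
      found[p] = false;
      hlen[p] = NA_INTEGER;
      ovl[p] = NA_INTEGER;
      ident[p] = NA_REAL;
      adj[p] = NA_REAL;
    }
  }
  return DataFrame::create(_["a"] = ia, _["b"] = ib, _["found"] = found,
                           _["identity"] = ident, _["hit_length"] = hlen,
                           _["max_overlap"] = ovl,
                           _["adjusted_similarity"] = adj,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// Junction tag scanning for the solo-LTR estimator.
//
// For each read (both strands) every boundary placement beta (read position
// directly after the LTR_3'end tag) with a qualifying LTR-tag hit
// (>= min_hit aligned columns at >= min_identity) and at least lx_flank
// bases of read remaining downstream is classified by the content of that
// downstream region:
//   LU: the 5'UTR tag aligns directly at beta (>= min_hit columns);
//   Lx: no placement of the 5'UTR tag within +-excl_slack of beta
//       qualifies.
// Requiring the same downstream window for both categories makes the two
// junction types equally detectable per read, so that expected counts obey
// E[Lx]/E[LU] = (N_full + N_solo)/N_full.  A read is counted once: LU takes
// precedence over Lx.  Returns 0 (neither), 1 (LU) or 2 (Lx) per read.
// [[Rcpp::export(name = "cpp_tag_scan")]]
IntegerVector cpp_tag_scan(CharacterVector reads, std::string ltr_tag,
                           std::string utr_tag, double min_identity,
                           int min_hit, int lx_flank, int excl_slack) {
  const std::vector<uint8_t> L = enc_seq(ltr_tag);
  const std::vector<uint8_t> U = enc_seq(utr_tag);
  const int lt = (int)L.size(), ut = (int)U.size();
  const long long id100 = (long long)std::llround(min_identity * 100.0);
  const int n = reads.size();
  IntegerVector out(n);

  auto tag_ok = [&](const std::vector<uint8_t> &R, const std::vector<uint8_t> &T,
                    int tstart) {
    // T placed so that T[0] sits at read position tstart (0-based, may be
    // negative); alignment clipped to the read
    const int R0 = std::max(0, tstart);
    const int R1 = std::min((int)R.size(), tstart + (int)T.size());
    const int len = R1 - R0;
    if (len < min_hit) return false;
    int mt = 0;
    for (int i = R0; i < R1; ++i) {
      const uint8_t x = R[i], y = T[i - tstart];
      if (x < 4 && x == y) ++mt;
    }
    return (long long)mt * 10000 >= id100 * (long long)len;
  };

  for (int r = 0; r < n; ++r) {
    std::vector<uint8_t> F = enc_seq(as<std::string>(reads[r]));
    int cat = 0;
    for (int strand = 0; strand < 2 && cat != 1; ++strand) {
      const std::vector<uint8_t> R = (strand == 0) ? F : rc_seq(F);
      const int rl = (int)R.size();
      // boundary beta = position after the LTR tag; tag occupies
      // [beta - lt, beta)
      for (int beta = min_hit; beta <= rl - lx_flank; ++beta) {
        if (!tag_ok(R, L, beta - lt)) continue;
        if (tag_ok(R, U, beta)) {
          cat = 1;  // LU
          break;
        }
        if (cat == 0) {
          bool utr_near = false;
          for (int o = beta - excl_slack; o <= beta + excl_slack; ++o) {
            if (o < -(ut - min_hit)) continue;
            if (tag_ok(R, U, o)) {
              utr_near = true;
              break;
            }
          }
          if (!utr_near) cat = 2;  // Lx candidate; LU may still override
        }
      }
    }
    out[r] = cat;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Contig consensus and per-read core (unmasked) spans.

// [[Rcpp::export(name = "cpp_consensus")]]
CharacterVector cpp_consensus(CharacterVector seqs, IntegerVector offsets,
                              IntegerVector strands, IntegerVector use_start,
                              IntegerVector use_end, int contig_len) {
  std::vector<std::array<int, 4>> counts(contig_len, {0, 0, 0, 0});
  const int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> s = enc_seq(as<std::string>(seqs[i]));
    if (strands[i] != 1) s = rc_seq(s);
    const int from = use_start[i] - 1, to = use_end[i];  // oriented read coords
    for (int k = from; k < to; ++k) {
      const int col = offsets[i] + k;
      if (col < 0 || col >= contig_len) continue;
      const uint8_t b = s[k];
      if (b < 4) counts[col][b] += 1;
    }
  }
  std::string cons(contig_len, 'N');
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int c = 0; c < contig_len; ++c) {
    int bi = -1, bc = 0;
    for (int b = 0; b < 4; ++b)
      if (counts[c][b] > bc) {
        bc = counts[c][b];
        bi = b;
      }
    if (bi >= 0) cons[c] = bases[bi];
  }
  return CharacterVector::create(cons);
}

// Longest segment of each read agreeing with the consensus at >= min_identity
// (same well-performing-interval scan as the hit search); coordinates are in
// oriented-read space (1-based inclusive).  Returns 0/0 when no segment of at
// least min_core columns qualifies.  Because a maximal interval over random
// flanking sequence can absorb chance matches while staying above the
// identity threshold, both core ends are trimmed until they open with
// `end_match` consecutive exact matches, which pins core boundaries to the
// true alignment ends to within a base or two.
// [[Rcpp::export(name = "cpp_core_spans")]]
DataFrame cpp_core_spans(std::string consensus, CharacterVector seqs,
                         IntegerVector offsets, IntegerVector strands,
                         double min_identity, int min_core,
                         int end_match = 4) {
  const std::vector<uint8_t> C = enc_seq(consensus);
  const long long id100 = (long long)std::llround(min_identity * 100.0);
  const int n = seqs.size();
  IntegerVector cs(n), ce(n);
  NumericVector cid(n);
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> s = enc_seq(as<std::string>(seqs[i]));
    if (strands[i] != 1) s = rc_seq(s);
    const int L = (int)s.size();
    std::vector<uint8_t> m(L, 0);
    for (int k = 0; k < L; ++k) {
      const int col = offsets[i] + k;
      if (col < 0 || col >= (int)C.size()) continue;
      const uint8_t x = s[k], y = C[col];
      m[k] = (x < 4 && x == y) ? 1 : 0;
    }
    SegHit h = longest_qualifying(m.data(), L, id100, min_core);
    if (h.found && end_match > 1) {
      int s = h.start, e = h.start + h.len - 1;
      auto clean = [&](int from) {
        for (int k = 0; k < end_match; ++k)
          if (from + k > e || !m[from + k]) return false;
        return true;
      };
      auto clean_rev = [&](int from) {
        for (int k = 0; k < end_match; ++k)
          if (from - k < s || !m[from - k]) return false;
        return true;
      };
      while (e - s + 1 >= min_core && !clean(s)) ++s;
      while (e - s + 1 >= min_core && !clean_rev(e)) --e;
      if (e - s + 1 >= min_core) {
        int matches = 0;
        for (int k = s; k <= e; ++k) matches += m[k];
        h.start = s;
        h.len = e - s + 1;
        h.matches = matches;
      } else {
        h.found = false;
      }
    }
    if (h.found) {
      cs[i] = h.start + 1;
      ce[i] = h.start + h.len;
      cid[i] = 100.0 * h.matches / h.len;
    } else {
      cs[i] = 0;
      ce[i] = 0;
      cid[i] = NA_REAL;
    }
  }
  return DataFrame::create(_["core_start"] = cs, _["core_end"] = ce,
                           _["core_identity"] = cid,
                           _["stringsAsFactors"] = false);
}
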