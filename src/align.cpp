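// Seed-and-extend local nucleotide aligner.
//
// Exact k-mer seeds on a flat open-addressing index of the subject set,
// diagonal clustering, then banded affine-gap Smith-Waterman around each
// seed cluster with full traceback (matches / alignment length are needed
// for the identity filters downstream). Both query strands are searched;
// subject coordinates are always reported on the forward subject strand.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <map>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = -0x3fffffff;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else: never matches, breaks seeds
  }
}

static std::vector<int8_t> encode(const char *s, size_t n) {
  std::vector<int8_t> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = (int8_t)base_code(s[i]);
  return v;
}

static std::vector<int8_t> revcomp(const std::vector<int8_t> &v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? (int8_t)-1 : (int8_t)(3 - b);
  }
  return r;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// ---- k-mer index over the subject set --------------------------------------

struct KmerIndex {
  int k;
  std::vector<uint64_t> ukey;          // unique k-mers, sorted
  std::vector<int64_t> start;          // offset into pos[] per unique k-mer
  std::vector<int32_t> cnt;
  std::vector<uint64_t> pos;           // packed (subject << 32 | position)
  std::vector<int64_t> table;          // open addressing: index+1 into ukey
  uint64_t mask;

  void build(const std::vector<std::vector<int8_t> > &subj, int k_) {
    k = k_;
    std::vector<std::pair<uint64_t, uint64_t> > kv;
    const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (size_t j = 0; j < subj.size(); ++j) {
      const std::vector<int8_t> &s = subj[j];
      if ((int)s.size() < k) continue;
      uint64_t key = 0;
      int run = 0;  // valid bases accumulated since last N
      for (size_t p = 0; p < s.size(); ++p) {
        if (s[p] < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)s[p]) & kmask;
        if (++run >= k) {
          uint64_t sp = p + 1 - k;
          kv.push_back(std::make_pair(key, ((uint64_t)j << 32) | sp));
        }
      }
    }
    std::sort(kv.begin(), kv.end());
    pos.resize(kv.size());
    for (size_t i = 0; i < kv.size(); ++i) {
      if (i == 0 || kv[i].first != kv[i - 1].first) {
        ukey.push_back(kv[i].first);
        start.push_back((int64_t)i);
        cnt.push_back(0);
      }
      cnt.back()++;
      pos[i] = kv[i].second;
    }
    uint64_t tsize = 16;
    while (tsize < ukey.size() * 2 + 1) tsize <<= 1;
    table.assign(tsize, 0);
    mask = tsize - 1;
    for (size_t i = 0; i < ukey.size(); ++i) {
      uint64_t h = splitmix64(ukey[i]) & mask;
      while (table[h]) h = (h + 1) & mask;
      table[h] = (int64_t)i + 1;
    }
  }

  // returns index into ukey or -1
  inline int64_t find(uint64_t key) const {
    if (table.empty()) return -1;
    uint64_t h = splitmix64(key) & mask;
    while (table[h]) {
      int64_t i = table[h] - 1;
      if (ukey[i] == key) return i;
      h = (h + 1) & mask;
    }
    return -1;
  }
};

// ---- banded affine-gap local DP with traceback -----------------------------

struct Aln {
  int score, matches, aln_len;
  int q_start, q_end, s_start, s_end;  // 0-based half-open
  bool valid;
  Aln() : score(0), matches(0), aln_len(0), q_start(0), q_end(0),
          s_start(0), s_end(0), valid(false) {}
};

// Alignment of q against s restricted to diagonals (s_pos - q_pos) in
// [dmin - band, dmax + band].
static Aln banded_sw(const std::vector<int8_t> &q, const std::vector<int8_t> &s,
                     int dmin, int dmax, int band,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int qlen = (int)q.size(), slen = (int)s.size();
  const int lo = dmin - band;            // minimum diagonal
  const int W = (dmax - dmin) + 2 * band + 1;
  const int go = gap_open + gap_extend;  // cost of opening a 1-base gap
  const int ge = gap_extend;

  // dir bits per cell: 0..3 H-source (0 stop, 1 diag, 2 left/E, 3 up/F),
  // bit2: E came from E (extension), bit3: F came from F
  std::vector<uint8_t> dir((size_t)(qlen + 1) * W, 0);
  std::vector<int> Hprev(W, 0), Hcur(W, 0), Eprev(W, NEG_INF), Ecur(W, NEG_INF),
      Fprev(W, NEG_INF), Fcur(W, NEG_INF);

  Aln best;
  int best_i = -1, best_c = -1, best_score = 0;

  for (int i = 1; i <= qlen; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    uint8_t *drow = &dir[(size_t)i * W];
    for (int c = 0; c < W; ++c) {
      int j = i + lo + c;  // subject position (1-based cell => s index j-1)
      if (j < 1 || j > slen) continue;
      // E: gap in query (consume subject base), from (i, c-1)
      int e = NEG_INF; bool e_ext = false;
      if (c > 0) {
        int open = Hcur[c - 1] - go;
        int ext = (Ecur[c - 1] == NEG_INF) ? NEG_INF : Ecur[c - 1] - ge;
        if (ext > open) { e = ext; e_ext = true; } else e = open;
      }
      // F: gap in subject (consume query base), from (i-1, c+1)
      int f = NEG_INF; bool f_ext = false;
      if (c + 1 < W) {
        int open = Hprev[c + 1] - go;
        int ext = (Fprev[c + 1] == NEG_INF) ? NEG_INF : Fprev[c + 1] - ge;
        if (ext > open) { f = ext; f_ext = true; } else f = open;
      }
      // diagonal from (i-1, c)
      int sub = (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ? match : mismatch;
      int d = Hprev[c] + sub;

      int h = 0; uint8_t src = 0;
      if (d > h) { h = d; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      Hcur[c] = h; Ecur[c] = e; Fcur[c] = f;
      drow[c] = src | (e_ext ? 4 : 0) | (f_ext ? 8 : 0);
      if (h > best_score) { best_score = h; best_i = i; best_c = c; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best_i < 0) return best;

  // traceback
  int i = best_i, c = best_c;
  int matches = 0, alen = 0;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  best.q_end = i; best.s_end = i + lo + c;
  while (true) {
    uint8_t d = dir[(size_t)i * W + c];
    if (state == 0) {
      uint8_t src = d & 3;
      if (src == 0) break;
      if (src == 1) {
        int j = i + lo + c;
        if (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ++matches;
        ++alen; --i;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // E: gap in query, move left
      ++alen;
      bool ext = (d & 4) != 0;
      --c;
      state = ext ? 1 : 0;
    } else {  // F: gap in subject, move up
      ++alen;
      bool ext = (d & 8) != 0;
      --i; ++c;
      state = ext ? 2 : 0;
    }
  }
  best.q_start = i; best.s_start = i + lo + c;
  best.score = best_score; best.matches = matches; best.aln_len = alen;
  best.valid = true;
  return best;
}

// ---- search ----------------------------------------------------------------

struct SeedHit { int32_t subj; int32_t diag; int32_t qp; };

// Ungapped extension in both directions from a seed at (qp, sp); X-drop 20.
static int ungapped_extend(const std::vector<int8_t> &q,
                           const std::vector<int8_t> &s,
                           int qp, int sp, int k, int match, int mismatch) {
  const int xdrop = 20;
  int score = k * match;  // the exact seed itself
  int best = score;
  for (int i = qp + k, j = sp + k;
       i < (int)q.size() && j < (int)s.size(); ++i, ++j) {
    score += (q[i] >= 0 && q[i] == s[j]) ? match : mismatch;
    if (score > best) best = score;
    if (best - score > xdrop) break;
  }
  score = best;
  for (int i = qp - 1, j = sp - 1; i >= 0 && j >= 0; --i, --j) {
    score += (q[i] >= 0 && q[i] == s[j]) ? match : mismatch;
    if (score > best) best = score;
    if (best - score > xdrop) break;
  }
  return best;
}

struct RawHit {
  int q, s; char strand;
  Aln a;
};

static void search_one_strand(const std::vector<int8_t> &q, char strand,
                              const std::vector<std::vector<int8_t> > &subj,
                              const KmerIndex &idx, int stride, int max_occ,
                              int max_clusters, int band, int min_ungapped,
                              int match, int mismatch, int gap_open, int gap_extend,
                              int qi, std::vector<RawHit> &out) {
  const int k = idx.k;
  const int qlen = (int)q.size();
  if (qlen < k) return;
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  std::vector<SeedHit> seeds;
  uint64_t key = 0; int run = 0;
  for (int p = 0; p < qlen; ++p) {
    if (q[p] < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)q[p]) & kmask;
    if (++run < k) continue;
    int qp = p + 1 - k;
    if (stride > 1 && (qp % stride) != 0) continue;
    int64_t u = idx.find(key);
    if (u < 0) continue;
    if (idx.cnt[u] > max_occ) continue;  // repeat masking
    int64_t st = idx.start[u];
    for (int32_t t = 0; t < idx.cnt[u]; ++t) {
      uint64_t packed = idx.pos[st + t];
      SeedHit sh;
      sh.subj = (int32_t)(packed >> 32);
      sh.diag = (int32_t)(packed & 0xffffffffULL) - qp;
      sh.qp = qp;
      seeds.push_back(sh);
    }
  }
  if (seeds.empty()) return;

  std::sort(seeds.begin(), seeds.end(), [](const SeedHit &a, const SeedHit &b) {
    if (a.subj != b.subj) return a.subj < b.subj;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qp < b.qp;
  });

  // cluster seeds on nearby diagonals of the same subject
  struct Cluster { int subj, dmin, dmax, count, qp; };
  std::vector<Cluster> clusters;
  for (size_t i = 0; i < seeds.size(); ++i) {
    if (!clusters.empty() && clusters.back().subj == seeds[i].subj &&
        seeds[i].diag - clusters.back().dmax <= band &&
        seeds[i].diag - clusters.back().dmin <= 2 * band) {
      clusters.back().dmax = std::max(clusters.back().dmax, (int)seeds[i].diag);
      clusters.back().count++;
    } else {
      Cluster c; c.subj = seeds[i].subj; c.dmin = seeds[i].diag;
      c.dmax = seeds[i].diag; c.count = 1; c.qp = seeds[i].qp;
      clusters.push_back(c);
    }
  }
  if ((int)clusters.size() > max_clusters) {
    std::sort(clusters.begin(), clusters.end(), [](const Cluster &a, const Cluster &b) {
      return a.count > b.count;
    });
    clusters.resize(max_clusters);
  }

  // best alignment per subject on this strand
  std::map<int, Aln> best_per_subj;
  for (size_t i = 0; i < clusters.size(); ++i) {
    const Cluster &cl = clusters[i];
    // BLAST-style pre-filter: on a single-diagonal cluster, a cheap
    // ungapped X-drop extension from the seed bounds the gapped score
    // from below; clusters that cannot reach min_ungapped skip the DP
    if (min_ungapped > 0 && cl.dmin == cl.dmax) {
      int ug = ungapped_extend(q, subj[cl.subj], cl.qp, cl.qp + cl.dmin, k,
                               match, mismatch);
      if (ug < min_ungapped) continue;
    }
    Aln a = banded_sw(q, subj[cl.subj], cl.dmin, cl.dmax, band,
                      match, mismatch, gap_open, gap_extend);
    if (!a.valid) continue;
    std::map<int, Aln>::iterator it = best_per_subj.find(cl.subj);
    if (it == best_per_subj.end() || a.score > it->second.score ||
        (a.score == it->second.score && a.s_start < it->second.s_start))
      best_per_subj[cl.subj] = a;
  }
  for (std::map<int, Aln>::iterator it = best_per_subj.begin();
       it != best_per_subj.end(); ++it) {
    RawHit h; h.q = qi; h.s = it->first; h.strand = strand; h.a = it->second;
    if (strand == '-') {
      // map query coordinates back onto the forward query
      int qs = h.a.q_start, qe = h.a.q_end;
      h.a.q_start = (int)q.size() - qe;
      h.a.q_end = (int)q.size() - qs;
    }
    out.push_back(h);
  }
}

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector queries, CharacterVector subjects,
                     int match, int mismatch, int gap_open, int gap_extend,
                     int seed_len, int band, int stride, int max_occ,
                     int max_clusters, int min_ungapped, bool best_only) {
  if (seed_len < 8 || seed_len > 31) stop("seed length must be in [8, 31]");
  std::vector<std::vector<int8_t> > subj(subjects.size());
  for (int j = 0; j < subjects.size(); ++j) {
    const char *s = CHAR(STRING_ELT(subjects, j));
    subj[j] = encode(s, LENGTH(STRING_ELT(subjects, j)));
  }
  KmerIndex idx;
  idx.build(subj, seed_len);

  std::vector<RawHit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    const char *qs = CHAR(STRING_ELT(queries, qi));
    std::vector<int8_t> q = encode(qs, LENGTH(STRING_ELT(queries, qi)));
    std::vector<RawHit> qhits;
    search_one_strand(q, '+', subj, idx, stride, max_occ, max_clusters, band,
                      min_ungapped, match, mismatch, gap_open, gap_extend,
                      qi, qhits);
    std::vector<int8_t> qrc = revcomp(q);
    search_one_strand(qrc, '-', subj, idx, stride, max_occ, max_clusters, band,
                      min_ungapped, match, mismatch, gap_open, gap_extend,
                      qi, qhits);
    if (best_only && !qhits.empty()) {
      size_t b = 0;
      for (size_t t = 1; t < qhits.size(); ++t) {
        const RawHit &x = qhits[t], &y = qhits[b];
        if (x.a.score > y.a.score ||
            (x.a.score == y.a.score &&
             (x.s < y.s || (x.s == y.s &&
              (x.a.s_start < y.a.s_start ||
               (x.a.s_start == y.a.s_start && x.strand == '+' && y.strand == '-'))))))
          b = t;
      }
      hits.push_back(qhits[b]);
    } else {
      for (size_t t = 0; t < qhits.size(); ++t) hits.push_back(qhits[t]);
    }
  }

  int n = (int)hits.size();
  IntegerVector q_(n), s_(n), score(n), matches(n), aln_len(n),
      qstart(n), qend(n), sstart(n), send(n);
  CharacterVector strand(n);
  for (int i = 0; i < n; ++i) {
    q_[i] = hits[i].q + 1; s_[i] = hits[i].s + 1;
    score[i] = hits[i].a.score; matches[i] = hits[i].a.matches;
    aln_len[i] = hits[i].a.aln_len;
    qstart[i] = hits[i].a.q_start; qend[i] = hits[i].a.q_end;
    sstart[i] = hits[i].a.s_start; send[i] = hits[i].a.s_end;
    strand[i] = (hits[i].strand == '+') ? "+" : "-";
  }
  return DataFrame::create(
      _["query"] = q_, _["subject"] = s_, _["score"] = score,
      _["matches"] = matches, _["aln_len"] = aln_len,
      _["q_start"] = qstart, _["q_end"] = qend,
      _["s_start"] = sstart, _["s_end"] = send, _["strand"] = strand,
      _["stringsAsFactors"] = false);
}
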