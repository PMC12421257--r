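// Compiled hot paths: 2-bit k-mer machinery, banded glocal alignment with
// traceback, read recruitment/alignment against a marker locus, pileup
// construction, and the k-mer equivalence-class index used for
// pseudoalignment. Everything user-facing wraps these from R.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int BASE_LUT_INIT = 0;
static int8_t BASE_LUT[256];

static void init_lut() {
  static bool done = false;
  if (done) return;
  for (int i = 0; i < 256; ++i) BASE_LUT[i] = -1;
  BASE_LUT[(unsigned char)'A'] = 0; BASE_LUT[(unsigned char)'a'] = 0;
  BASE_LUT[(unsigned char)'C'] = 1; BASE_LUT[(unsigned char)'c'] = 1;
  BASE_LUT[(unsigned char)'G'] = 2; BASE_LUT[(unsigned char)'g'] = 2;
  BASE_LUT[(unsigned char)'T'] = 3; BASE_LUT[(unsigned char)'t'] = 3;
  done = true;
}

static inline uint64_t rc_kmer(uint64_t km, int k) {
  // complement then reverse 2-bit fields
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (km & 3ULL));
    km >>= 2;
  }
  return rc;
}

// all valid k-mers of seq with their 0-based positions
static void kmers_of(const std::string& s, int k,
                     std::vector<uint64_t>& kms, std::vector<int>& pos) {
  init_lut();
  kms.clear(); pos.clear();
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t km = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int8_t b = BASE_LUT[(unsigned char)s[i]];
    if (b < 0) { run = 0; km = 0; continue; }
    km = ((km << 2) | (uint64_t)b) & mask;
    if (++run >= k) { kms.push_back(km); pos.push_back(i - k + 1); }
  }
}

// forward and reverse-complement k-mers computed with a rolling update
static void kmers_of_both(const std::string& s, int k,
                          std::vector<uint64_t>& fwd,
                          std::vector<uint64_t>& rc,
                          std::vector<int>& pos) {
  init_lut();
  fwd.clear(); rc.clear(); pos.clear();
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t km = 0, rk = 0;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const int shift = 2 * (k - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int8_t b = BASE_LUT[(unsigned char)s[i]];
    if (b < 0) { run = 0; km = 0; rk = 0; continue; }
    km = ((km << 2) | (uint64_t)b) & mask;
    rk = (rk >> 2) | ((3ULL - (uint64_t)b) << shift);
    if (++run >= k) {
      fwd.push_back(km); rc.push_back(rk); pos.push_back(i - k + 1);
    }
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// ---------------------------------------------------------------------------
// Banded glocal alignment: pattern global, subject free end gaps.
// Band over diagonals d = j - i in [dlo, dhi]. Linear gap penalty.
// Returns score, matches, columns, subject start/end (0-based half-open),
// optionally a projection of the pattern onto subject coordinates.
// ---------------------------------------------------------------------------
struct AlnResult {
  int score, matches, columns, sub_start, sub_end;
  bool ok;
  std::string proj;       // one char per consumed subject position
  std::string proj_aux;   // parallel auxiliary chars (e.g. quals)
  std::vector<std::pair<int, std::string>> ins; // subject pos -> inserted seq
};

static const int NEG_INF = -1000000000;

static AlnResult banded_glocal(const std::string& P, const std::string& S,
                               int dlo, int dhi,
                               int match, int mismatch, int gap,
                               bool want_proj, const std::string& aux,
                               bool local = false) {
  AlnResult res; res.ok = false;
  const int m = (int)P.size(), n = (int)S.size();
  res.score = NEG_INF; res.matches = 0; res.columns = 0;
  res.sub_start = 0; res.sub_end = 0;
  if (m == 0 || n == 0) return res;
  dlo = std::max(dlo, -m); dhi = std::min(dhi, n);
  if (dlo > dhi) return res;
  const int W = dhi - dlo + 1;
  std::vector<int> dp((size_t)(m + 1) * W, NEG_INF);
  std::vector<int8_t> tb((size_t)(m + 1) * W, 0); // 1 diag, 2 up, 3 left
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - i - dlo); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= n && (j - i) >= dlo && (j - i) <= dhi;
  };
  // row 0: free leading subject gap (and, in local mode, free pattern start)
  for (int j = std::max(0, dlo); j <= std::min(n, dhi); ++j) dp[idx(0, j)] = 0;
  for (int i = 1; i <= m; ++i) {
    const char pc = P[i - 1];
    int jlo = std::max(0, i + dlo), jhi = std::min(n, i + dhi);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG_INF; int8_t t = 0;
      if (j >= 1 && inband(i - 1, j - 1) && dp[idx(i - 1, j - 1)] > NEG_INF) {
        int sc = dp[idx(i - 1, j - 1)] + (pc == S[j - 1] ? match : mismatch);
        if (sc > best) { best = sc; t = 1; }
      }
      if (inband(i - 1, j) && dp[idx(i - 1, j)] > NEG_INF) {
        int sc = dp[idx(i - 1, j)] + gap; // pattern base vs subject gap
        if (sc > best) { best = sc; t = 2; }
      }
      if (j >= 1 && inband(i, j - 1) && dp[idx(i, j - 1)] > NEG_INF) {
        int sc = dp[idx(i, j - 1)] + gap; // subject base vs pattern gap
        if (sc > best) { best = sc; t = 3; }
      }
      if (local && best < 0) { best = 0; t = 0; } // fresh local start
      if (best > NEG_INF) { dp[idx(i, j)] = best; tb[idx(i, j)] = t; }
    }
  }
  int bj = -1, bi = m, bs = NEG_INF;
  if (local) {
    // best cell anywhere; ties resolved toward longer alignments
    for (int i = 1; i <= m; ++i) {
      int jlo = std::max(0, i + dlo), jhi = std::min(n, i + dhi);
      for (int j = jlo; j <= jhi; ++j) {
        int v = dp[idx(i, j)];
        if (v > bs || (v == bs && (i > bi || (i == bi && j > bj)))) {
          bs = v; bi = i; bj = j;
        }
      }
    }
    if (bj < 0 || bs <= 0) return res;
  } else {
    // best end over last row (free trailing subject gap)
    for (int j = std::max(0, m + dlo); j <= std::min(n, m + dhi); ++j) {
      if (dp[idx(m, j)] > bs) { bs = dp[idx(m, j)]; bj = j; }
    }
    if (bj < 0) return res;
  }
  res.score = bs; res.sub_end = bj;
  // traceback
  int i = bi, j = bj;
  std::string proj, proj_aux;
  std::vector<std::pair<int, std::string>> ins;
  std::string cur_ins;
  while (i > 0) {
    int8_t t = tb[idx(i, j)];
    if (t == 0) break; // reached row-0 style cell
    if (t == 1) {
      if (!cur_ins.empty()) {
        std::reverse(cur_ins.begin(), cur_ins.end());
        ins.push_back({j, cur_ins}); cur_ins.clear();
      }
      res.columns++; if (P[i - 1] == S[j - 1]) res.matches++;
      if (want_proj) {
        proj.push_back(P[i - 1]);
        proj_aux.push_back(aux.empty() ? '~' : aux[i - 1]);
      }
      --i; --j;
    } else if (t == 2) { // insertion in pattern relative to subject
      res.columns++;
      if (want_proj) cur_ins.push_back(P[i - 1]);
      --i;
    } else { // deletion in pattern: subject base consumed
      res.columns++;
      if (want_proj) { proj.push_back('-'); proj_aux.push_back('~'); }
      --j;
    }
  }
  if (!cur_ins.empty()) {
    std::reverse(cur_ins.begin(), cur_ins.end());
    ins.push_back({j, cur_ins});
  }
  res.sub_start = j;
  if (want_proj) {
    std::reverse(proj.begin(), proj.end());
    std::reverse(proj_aux.begin(), proj_aux.end());
    res.proj = proj; res.proj_aux = proj_aux;
    std::reverse(ins.begin(), ins.end());
    res.ins = ins;
  }
  res.ok = true;
  return res;
}

// [[Rcpp::export]]
List cpp_align_glocal(std::string pattern, std::string subject,
                      int dlo, int dhi,
                      int match = 1, int mismatch = -1, int gap = -2,
                      bool local = false) {
  AlnResult r = banded_glocal(pattern, subject, dlo, dhi,
                              match, mismatch, gap, false, "", local);
  return List::create(_["ok"] = r.ok, _["score"] = r.score,
                      _["matches"] = r.matches, _["columns"] = r.columns,
                      _["sub_start"] = r.sub_start, _["sub_end"] = r.sub_end);
}

// ---------------------------------------------------------------------------
// Seed anchoring: exact k-mer hits of the seed on a contig, both strands.
// Returns estimated locus start diagonals for candidate-window clustering.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame cpp_seed_anchors(std::string contig, std::string seed,
                           int k = 15, int stride = 25) {
  std::vector<uint64_t> skm; std::vector<int> spos;
  kmers_of(seed, k, skm, spos);
  std::unordered_map<uint64_t, int> fwd, rev;
  for (size_t i = 0; i < skm.size(); i += stride) {
    if (!fwd.count(skm[i])) fwd[skm[i]] = spos[i];
    uint64_t rc = rc_kmer(skm[i], k);
    if (!rev.count(rc)) rev[rc] = spos[i];
  }
  std::vector<uint64_t> ckm; std::vector<int> cpos;
  kmers_of(contig, k, ckm, cpos);
  std::vector<int> est_start; std::vector<int> strand; std::vector<int> hitpos;
  const int L = (int)seed.size();
  for (size_t i = 0; i < ckm.size(); ++i) {
    auto f = fwd.find(ckm[i]);
    if (f != fwd.end()) {
      est_start.push_back(cpos[i] - f->second);
      strand.push_back(1); hitpos.push_back(cpos[i]);
    }
    auto r = rev.find(ckm[i]);
    if (r != rev.end()) {
      // contig k-mer equals revcomp of seed k-mer at seed pos s:
      // locus end (exclusive) = cpos + k + s  => start = end - L
      est_start.push_back(cpos[i] + k + r->second - L);
      strand.push_back(-1); hitpos.push_back(cpos[i]);
    }
  }
  return DataFrame::create(_["est_start"] = est_start, _["strand"] = strand,
                           _["pos"] = hitpos);
}

// ---------------------------------------------------------------------------
// Read recruitment: count shared canonical k-mers with the locus.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cpp_shared_kmers(CharacterVector reads, std::string locus, int k) {
  std::vector<uint64_t> lf, lr; std::vector<int> lpos;
  kmers_of_both(locus, k, lf, lr, lpos);
  std::unordered_set<uint64_t> set;
  set.reserve(lf.size() * 2);
  for (size_t i = 0; i < lf.size(); ++i) set.insert(std::min(lf[i], lr[i]));
  const int n = reads.size();
  IntegerVector out(n);
  std::vector<uint64_t> rf, rr; std::vector<int> rpos;
  for (int i = 0; i < n; ++i) {
    std::string r = as<std::string>(reads[i]);
    kmers_of_both(r, k, rf, rr, rpos);
    int c = 0;
    for (size_t j = 0; j < rf.size(); ++j)
      if (set.count(std::min(rf[j], rr[j]))) ++c;
    out[i] = c;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read-vs-locus alignment. Anchors each read by exact k-mers (both
// orientations), clips to the locus, tries an ungapped comparison first and
// falls back to banded DP when the ungapped identity is poor (indels).
// Mapping quality = min(60, 4 * (S1 - S2)) against competitor loci
// (paralogs); 60 when no competitor is given.
// ---------------------------------------------------------------------------
struct AnchorMap {
  std::unordered_map<uint64_t, int> pos; // fwd k-mer -> first position
  int k;
  void build(const std::string& s, int k_) {
    k = k_;
    std::vector<uint64_t> km; std::vector<int> p;
    kmers_of(s, k_, km, p);
    for (size_t i = 0; i < km.size(); ++i)
      if (!pos.count(km[i])) pos[km[i]] = p[i];
  }
};

// vote on (orientation, offset); returns true if anchored
static bool anchor_read(const std::string& read, const AnchorMap& am,
                        bool& rc_out, int& offset_out) {
  std::vector<uint64_t> kf, kr; std::vector<int> p;
  std::unordered_map<int, int> votes_f, votes_r;
  kmers_of_both(read, am.k, kf, kr, p);
  for (size_t i = 0; i < kf.size(); ++i) {
    auto it = am.pos.find(kf[i]);
    if (it != am.pos.end()) votes_f[it->second - p[i]]++;
    auto jt = am.pos.find(kr[i]);
    if (jt != am.pos.end()) {
      // rc of read k-mer at read pos p matches locus fwd at pos q:
      // reversed read start offset = q - (len - p - k)
      int off = jt->second - ((int)read.size() - p[i] - am.k);
      votes_r[off]++;
    }
  }
  int bf = -1, bo = 0; bool rc = false;
  for (auto& kv : votes_f) if (kv.second > bf) { bf = kv.second; bo = kv.first; rc = false; }
  for (auto& kv : votes_r) if (kv.second > bf) { bf = kv.second; bo = kv.first; rc = true; }
  if (bf < 1) return false;
  rc_out = rc; offset_out = bo;
  return true;
}

// ungapped compare of read (already oriented) at offset on locus, clipping
// overhangs; returns matches, overlap length, and clip amounts
static void ungapped_stats(const std::string& read, const std::string& locus,
                           int offset, int& matches, int& overlap,
                           int& clip5, int& clip3) {
  const int L = (int)locus.size(), n = (int)read.size();
  int rs = std::max(0, -offset);              // first read base used
  int re = std::min(n, L - offset);           // one past last read base used
  clip5 = rs; clip3 = n - re;
  overlap = std::max(0, re - rs); matches = 0;
  for (int i = rs; i < re; ++i)
    if (read[i] == locus[offset + i]) ++matches;
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector quals,
                     std::string locus, int k = 21,
                     List competitors = List::create(),
                     int band = 8, double min_identity = 0.8,
                     int match = 1, int mismatch = -1, int gap = -2) {
  AnchorMap am; am.build(locus, k);
  std::vector<AnchorMap> comp_am;
  std::vector<std::string> comp_seq;
  for (int c = 0; c < competitors.size(); ++c) {
    comp_seq.push_back(as<std::string>(competitors[c]));
    AnchorMap a; a.build(comp_seq.back(), k);
    comp_am.push_back(a);
  }
  const int n = reads.size();
  std::vector<int> r_idx, r_start, r_mq, r_score, r_clip;
  std::vector<double> r_ident;
  std::vector<std::string> r_proj, r_qproj, r_ins;
  std::vector<int> r_strand;
  int n_unanchored = 0, n_lowident = 0;
  const bool have_quals = quals.size() == n;

  for (int i = 0; i < n; ++i) {
    std::string read = as<std::string>(reads[i]);
    std::string q = have_quals ? as<std::string>(quals[i]) : std::string(read.size(), 'I');
    bool rc; int offset;
    if (!anchor_read(read, am, rc, offset)) { n_unanchored++; continue; }
    if (rc) { read = revcomp_str(read); std::reverse(q.begin(), q.end()); }
    int matches, overlap, clip5, clip3;
    ungapped_stats(read, locus, offset, matches, overlap, clip5, clip3);
    int score; double ident;
    std::string proj, qproj, insstr;
    int start;
    bool used_dp = false;
    if (overlap > 0 && (double)matches / overlap >= 0.9) {
      // fast path: no indel evidence
      score = matches * match + (overlap - matches) * mismatch;
      ident = (double)matches / overlap;
      start = offset + clip5;
      proj = read.substr(clip5, overlap);
      qproj = q.substr(clip5, overlap);
    } else {
      // banded DP on the clipped read against a padded locus window
      used_dp = true;
      int ws = std::max(0, offset - band), we = std::min((int)locus.size(),
                       offset + (int)read.size() + band);
      std::string sub = locus.substr(ws, we - ws);
      std::string pat = read.substr(clip5, read.size() - clip5 - clip3);
      std::string paux = q.substr(clip5, read.size() - clip5 - clip3);
      int exp_off = offset + clip5 - ws;
      AlnResult r = banded_glocal(pat, sub, exp_off - band, exp_off + band,
                                  match, mismatch, gap, true, paux);
      if (!r.ok || r.columns == 0) { n_unanchored++; continue; }
      score = r.score;
      ident = (double)r.matches / r.columns;
      start = ws + r.sub_start;
      proj = r.proj; qproj = r.proj_aux;
      std::string is;
      for (auto& pr : r.ins) {
        if (!is.empty()) is.push_back(',');
        is += std::to_string(ws + pr.first) + ":" + pr.second;
      }
      insstr = is;
    }
    (void)used_dp;
    if (ident < min_identity) { n_lowident++; continue; }
    // mapping quality vs competitors
    int mq = 60;
    if (!comp_am.empty()) {
      int s2 = NEG_INF;
      for (size_t c = 0; c < comp_am.size(); ++c) {
        bool crc; int coff;
        std::string rr = read; // already oriented vs locus; try both anyway
        if (!anchor_read(rr, comp_am[c], crc, coff)) continue;
        std::string orr = crc ? revcomp_str(rr) : rr;
        int cm, cov, c5, c3;
        ungapped_stats(orr, comp_seq[c], coff, cm, cov, c5, c3);
        int cs = cm * match + (cov - cm) * mismatch;
        if (cs > s2) s2 = cs;
      }
      if (s2 > NEG_INF) mq = std::max(0, std::min(60, 4 * (score - s2)));
    }
    r_idx.push_back(i + 1); r_start.push_back(start);
    r_mq.push_back(mq); r_score.push_back(score);
    r_ident.push_back(ident); r_strand.push_back(rc ? -1 : 1);
    r_clip.push_back(clip5 + clip3);
    r_proj.push_back(proj); r_qproj.push_back(qproj); r_ins.push_back(insstr);
  }
  return List::create(
    _["read"] = r_idx, _["start"] = r_start, _["strand"] = r_strand,
    _["mq"] = r_mq, _["score"] = r_score, _["identity"] = r_ident,
    _["clipped"] = r_clip, _["proj"] = r_proj, _["qual"] = r_qproj,
    _["ins"] = r_ins,
    _["n_unaligned"] = n_unanchored + n_lowident,
    _["n_unanchored"] = n_unanchored, _["n_low_identity"] = n_lowident);
}

// ---------------------------------------------------------------------------
// Pileup from locus-projected alignments. Rows: locus positions; columns
// A+,C+,G+,T+,del+,A-,C-,G-,T-,del-. Base-quality and MQ filters applied.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_pileup(IntegerVector start, CharacterVector proj,
                         CharacterVector qual, IntegerVector strand,
                         IntegerVector mq, int locus_len,
                         int min_bq = 20, int min_mq = 30) {
  init_lut();
  IntegerMatrix out(locus_len, 10);
  const int n = start.size();
  for (int i = 0; i < n; ++i) {
    if (mq[i] < min_mq) continue;
    std::string p = as<std::string>(proj[i]);
    std::string q = as<std::string>(qual[i]);
    const int off = strand[i] > 0 ? 0 : 5;
    for (size_t j = 0; j < p.size(); ++j) {
      int pos = start[i] + (int)j;
      if (pos < 0 || pos >= locus_len) continue;
      if (p[j] == '-') { out(pos, 4 + off)++; continue; }
      if ((int)q[j] - 33 < min_bq) continue;
      int8_t b = BASE_LUT[(unsigned char)p[j]];
      if (b < 0) continue;
      out(pos, b + off)++;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Quantification index: canonical k-mers -> equivalence classes of members.
// ---------------------------------------------------------------------------
struct QuantIndex {
  int k;
  std::vector<std::string> members;
  std::vector<std::string> joined;
  std::unordered_map<uint64_t, int> kmer2class;
  std::vector<std::vector<int>> classes; // 0-based member indices
  std::vector<AnchorMap> anchors;        // per member, fwd k-mers of joined
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector member_ids, CharacterVector joined_seqs,
                     int k = 31) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<QuantIndex> xp(new QuantIndex(), true);
  QuantIndex& qi = *xp;
  qi.k = k;
  const int M = member_ids.size();
  std::unordered_map<uint64_t, std::vector<int>> km2members;
  for (int m = 0; m < M; ++m) {
    qi.members.push_back(as<std::string>(member_ids[m]));
    qi.joined.push_back(as<std::string>(joined_seqs[m]));
    AnchorMap am; am.build(qi.joined.back(), k);
    qi.anchors.push_back(am);
    std::vector<uint64_t> kf, kr; std::vector<int> pos;
    kmers_of_both(qi.joined.back(), k, kf, kr, pos);
    std::unordered_set<uint64_t> seen;
    for (size_t i = 0; i < kf.size(); ++i) {
      uint64_t c = std::min(kf[i], kr[i]);
      if (seen.insert(c).second) km2members[c].push_back(m);
    }
  }
  // assign equivalence classes by member-set key
  std::unordered_map<std::string, int> key2class;
  for (auto& kv : km2members) {
    std::string key;
    for (int m : kv.second) { key += std::to_string(m); key.push_back(','); }
    auto it = key2class.find(key);
    int cid;
    if (it == key2class.end()) {
      cid = (int)qi.classes.size();
      key2class[key] = cid;
      qi.classes.push_back(kv.second);
    } else cid = it->second;
    qi.kmer2class[kv.first] = cid;
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp_) {
  XPtr<QuantIndex> xp(xp_);
  List cls(xp->classes.size());
  for (size_t i = 0; i < xp->classes.size(); ++i) {
    IntegerVector v(xp->classes[i].size());
    for (size_t j = 0; j < xp->classes[i].size(); ++j) v[j] = xp->classes[i][j] + 1;
    cls[i] = v;
  }
  return List::create(_["k"] = xp->k,
                      _["members"] = wrap(xp->members),
                      _["n_kmers"] = (double)xp->kmer2class.size(),
                      _["classes"] = cls);
}

// candidate members of a single sequence; returns counts per member and total
static void classify_seq(const QuantIndex& qi, const std::string& s,
                         std::vector<int>& hits, int& total) {
  std::vector<uint64_t> kf, kr; std::vector<int> pos;
  kmers_of_both(s, qi.k, kf, kr, pos);
  total = 0;
  std::fill(hits.begin(), hits.end(), 0);
  for (size_t i = 0; i < kf.size(); ++i) {
    auto it = qi.kmer2class.find(std::min(kf[i], kr[i]));
    if (it == qi.kmer2class.end()) continue;
    ++total;
    for (int m : qi.classes[it->second]) hits[m]++;
  }
}

static std::vector<int> candidates_from_hits(const std::vector<int>& hits,
                                             int total, double majority) {
  std::vector<int> cand;
  if (total == 0) return cand;
  for (size_t m = 0; m < hits.size(); ++m)
    if (hits[m] == total) cand.push_back((int)m);
  if (cand.empty()) {
    double thr = majority * total;
    for (size_t m = 0; m < hits.size(); ++m)
      if (hits[m] >= thr && hits[m] > 0) cand.push_back((int)m);
  }
  return cand;
}

// [[Rcpp::export]]
List cpp_pseudoalign(SEXP xp_, CharacterVector reads1, CharacterVector reads2,
                     double majority = 0.8) {
  XPtr<QuantIndex> xp(xp_);
  const QuantIndex& qi = *xp;
  const int n = reads1.size();
  const bool paired = reads2.size() == n;
  List out(n);
  std::vector<int> hits(qi.members.size());
  for (int i = 0; i < n; ++i) {
    int t1 = 0;
    classify_seq(qi, as<std::string>(reads1[i]), hits, t1);
    std::vector<int> c1 = candidates_from_hits(hits, t1, majority);
    std::vector<int> cand;
    if (paired) {
      int t2 = 0;
      classify_seq(qi, as<std::string>(reads2[i]), hits, t2);
      std::vector<int> c2 = candidates_from_hits(hits, t2, majority);
      if (!c1.empty() && !c2.empty()) {
        std::set_intersection(c1.begin(), c1.end(), c2.begin(), c2.end(),
                              std::back_inserter(cand));
      } else cand = c1.empty() ? c2 : c1;
    } else cand = c1;
    IntegerVector v(cand.size());
    for (size_t j = 0; j < cand.size(); ++j) v[j] = cand[j] + 1;
    out[i] = v;
  }
  return out;
}

// identity of one (oriented automatically) sequence against one member
static double member_identity(const QuantIndex& qi, int m,
                              const std::string& read, int band) {
  bool rc; int offset;
  if (!anchor_read(read, qi.anchors[m], rc, offset)) return 0.0;
  std::string r = rc ? revcomp_str(read) : read;
  const std::string& S = qi.joined[m];
  int matches, overlap, clip5, clip3;
  ungapped_stats(r, S, offset, matches, overlap, clip5, clip3);
  if (overlap <= 0) return 0.0;
  double id0 = (double)matches / overlap;
  if (id0 >= 0.9) return id0;
  int ws = std::max(0, offset - band);
  int we = std::min((int)S.size(), offset + (int)r.size() + band);
  std::string sub = S.substr(ws, we - ws);
  std::string pat = r.substr(clip5, r.size() - clip5 - clip3);
  int exp_off = offset + clip5 - ws;
  AlnResult a = banded_glocal(pat, sub, exp_off - band, exp_off + band,
                              1, -1, -2, false, "");
  if (!a.ok || a.columns == 0) return id0;
  return std::max(id0, (double)a.matches / a.columns);
}

// [[Rcpp::export]]
List cpp_validate_identity(SEXP xp_, CharacterVector reads1,
                           CharacterVector reads2, List candidates,
                           double min_identity = 0.95, int band = 8) {
  XPtr<QuantIndex> xp(xp_);
  const QuantIndex& qi = *xp;
  const int n = reads1.size();
  const bool paired = reads2.size() == n;
  List keep(n), ident(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector cand = candidates[i];
    std::vector<int> kp; std::vector<double> id;
    std::string r1 = as<std::string>(reads1[i]);
    std::string r2 = paired ? as<std::string>(reads2[i]) : std::string();
    for (int j = 0; j < cand.size(); ++j) {
      int m = cand[j] - 1;
      double d1 = member_identity(qi, m, r1, band);
      double d;
      if (paired) {
        double d2 = member_identity(qi, m, r2, band);
        // pooled identity over both mates
        d = (d1 * r1.size() + d2 * r2.size()) / (r1.size() + r2.size());
      } else d = d1;
      if (d >= min_identity) { kp.push_back(cand[j]); id.push_back(d); }
    }
    keep[i] = wrap(kp); ident[i] = wrap(id);
  }
  return List::create(_["candidates"] = keep, _["identity"] = ident);
}
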