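#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Residue encoding: A=0 C=1 G=2 T=3, anything else (incl. N) = 4.
// Code 4 never matches anything, including itself.
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

static std::vector<int> revcomp_enc(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? 3 - c : 4;
  }
  return r;
}

// ---------------------------------------------------------------------------
// Lexicographic alignment value: maximize score, then matches, then minimize
// columns.  Identity = matches / columns is then well-defined without a
// traceback tie-break.
// ---------------------------------------------------------------------------
struct Tri {
  int s;    // affine score
  int mt;   // matching columns
  int cols; // alignment columns
};

static const int NEG = -1000000000;
static inline Tri tri_neg() { return Tri{NEG, 0, 0}; }

static inline bool tri_less(const Tri& a, const Tri& b) {
  if (a.s != b.s) return a.s < b.s;
  if (a.mt != b.mt) return a.mt < b.mt;
  return a.cols > b.cols;
}
static inline Tri tri_max(const Tri& a, const Tri& b) { return tri_less(a, b) ? b : a; }

struct ScoreParams {
  int match;      // +1
  int mismatch;   // -1 (signed score contribution)
  int gap_open;   // 2 (cost)
  int gap_extend; // 1 (cost); gap of length g costs gap_open + g*gap_extend
};

// Glocal alignment: pattern end-to-end, free ends on the subject.
// Returns the lexicographically optimal (score, matches, columns).
static Tri glocal_align(const int* pat, int m, const int* sub, int n,
                        const ScoreParams& sp) {
  const int gfirst = sp.gap_open + sp.gap_extend;
  std::vector<Tri> Hp(n + 1), Ep(n + 1), Fp(n + 1), H(n + 1), E(n + 1), F(n + 1);
  // Row 0: virtual start (free subject prefix) for H; E/F invalid.
  for (int j = 0; j <= n; ++j) { Hp[j] = Tri{0, 0, 0}; Ep[j] = tri_neg(); Fp[j] = tri_neg(); }
  for (int i = 1; i <= m; ++i) {
    H[0] = tri_neg(); E[0] = tri_neg();
    {
      Tri c = tri_max(Hp[0], Ep[0]);
      if (c.s > NEG / 2) c.s -= gfirst;
      Tri c2 = Fp[0];
      if (c2.s > NEG / 2) c2.s -= sp.gap_extend;
      Tri f = tri_max(c, c2);
      if (f.s > NEG / 2) f.cols += 1;
      F[0] = f;
    }
    const int pc = pat[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool is_match = (pc < 4) && (pc == sub[j - 1]);
      Tri d = tri_max(tri_max(Hp[j - 1], Ep[j - 1]), Fp[j - 1]);
      if (d.s > NEG / 2) {
        d.s += is_match ? sp.match : sp.mismatch;
        d.mt += is_match ? 1 : 0;
        d.cols += 1;
      }
      H[j] = d;
      Tri e1 = tri_max(H[j - 1], F[j - 1]);
      if (e1.s > NEG / 2) e1.s -= gfirst;
      Tri e2 = E[j - 1];
      if (e2.s > NEG / 2) e2.s -= sp.gap_extend;
      Tri e = tri_max(e1, e2);
      if (e.s > NEG / 2) e.cols += 1;
      E[j] = e;
      Tri f1 = tri_max(Hp[j], Ep[j]);
      if (f1.s > NEG / 2) f1.s -= gfirst;
      Tri f2 = Fp[j];
      if (f2.s > NEG / 2) f2.s -= sp.gap_extend;
      Tri f = tri_max(f1, f2);
      if (f.s > NEG / 2) f.cols += 1;
      F[j] = f;
    }
    std::swap(Hp, H); std::swap(Ep, E); std::swap(Fp, F);
  }
  Tri best = tri_neg();
  for (int j = 0; j <= n; ++j) {
    best = tri_max(best, Hp[j]);
    best = tri_max(best, Ep[j]);
    best = tri_max(best, Fp[j]);
  }
  return best;
}

// Best local (Smith-Waterman-style) alignment under the same lexicographic
// objective; used for top-HSP identity reporting.
static Tri local_align(const std::vector<int>& a, const std::vector<int>& b,
                       const ScoreParams& sp) {
  const int m = (int)a.size(), n = (int)b.size();
  const int gfirst = sp.gap_open + sp.gap_extend;
  std::vector<Tri> Hp(n + 1), Ep(n + 1), Fp(n + 1), H(n + 1), E(n + 1), F(n + 1);
  for (int j = 0; j <= n; ++j) { Hp[j] = Tri{0, 0, 0}; Ep[j] = tri_neg(); Fp[j] = tri_neg(); }
  Tri best = tri_neg();
  for (int i = 1; i <= m; ++i) {
    H[0] = Tri{0, 0, 0}; E[0] = tri_neg(); F[0] = tri_neg();
    const int pc = a[i - 1];
    for (int j = 1; j <= n; ++j) {
      const bool is_match = (pc < 4) && (pc == b[j - 1]);
      Tri d = tri_max(tri_max(Hp[j - 1], Ep[j - 1]), Fp[j - 1]);
      if (d.s > NEG / 2) {
        d.s += is_match ? sp.match : sp.mismatch;
        d.mt += is_match ? 1 : 0;
        d.cols += 1;
      }
      d = tri_max(d, Tri{0, 0, 0}); // local restart
      H[j] = d;
      Tri e1 = tri_max(H[j - 1], F[j - 1]);
      if (e1.s > NEG / 2) e1.s -= gfirst;
      Tri e2 = E[j - 1];
      if (e2.s > NEG / 2) e2.s -= sp.gap_extend;
      Tri e = tri_max(e1, e2);
      if (e.s > NEG / 2) e.cols += 1;
      E[j] = e;
      Tri f1 = tri_max(Hp[j], Ep[j]);
      if (f1.s > NEG / 2) f1.s -= gfirst;
      Tri f2 = Fp[j];
      if (f2.s > NEG / 2) f2.s -= sp.gap_extend;
      Tri f = tri_max(f1, f2);
      if (f.s > NEG / 2) f.cols += 1;
      F[j] = f;
      if (H[j].cols > 0) best = tri_max(best, H[j]);
    }
    std::swap(Hp, H); std::swap(Ep, E); std::swap(Fp, F);
  }
  if (best.s <= NEG / 2) best = Tri{0, 0, 0}; // no aligned column at all
  return best;
}

// ---------------------------------------------------------------------------
// Blocked Myers bit-parallel semi-global edit distance (unit costs, free text
// ends).  Returns the minimum over all end positions; optionally records text
// positions whose ending distance is <= keep_max (candidate collection).
// ---------------------------------------------------------------------------
struct MyersPattern {
  int m = 0;
  int blocks = 0;
  int last_bits = 0;
  std::vector<uint64_t> peq; // blocks x 5 (A C G T other)
  std::vector<uint64_t> VP, VN;
  void build(const int* pat, int len) {
    m = len;
    blocks = (m + 63) / 64;
    last_bits = m - 64 * (blocks - 1);
    peq.assign((size_t)blocks * 5, 0);
    VP.resize(blocks); VN.resize(blocks);
    for (int i = 0; i < m; ++i) {
      int r = i / 64, bit = i % 64;
      int c = pat[i];
      if (c < 4) peq[(size_t)r * 5 + c] |= (1ULL << bit);
      // code 4 (N) matches nothing: its row stays 0 in every Peq
    }
  }
};

static int myers_scan(MyersPattern& mp, const int* text, int len,
                      int keep_max, std::vector<int>* end_pos) {
  const int b = mp.blocks;
  std::fill(mp.VP.begin(), mp.VP.end(), ~0ULL);
  std::fill(mp.VN.begin(), mp.VN.end(), 0ULL);
  uint64_t* VP = mp.VP.data();
  uint64_t* VN = mp.VN.data();
  int score = mp.m;
  int dmin = mp.m;
  const uint64_t last_hb = 1ULL << (mp.last_bits - 1);
  for (int j = 0; j < len; ++j) {
    const int tc = text[j];
    int hin = 0;
    for (int r = 0; r < b; ++r) {
      uint64_t Eq = mp.peq[(size_t)r * 5 + tc];
      if (hin < 0) Eq |= 1ULL;
      const uint64_t vp = VP[r], vn = VN[r];
      uint64_t X = Eq | vn;
      uint64_t D0 = (((Eq & vp) + vp) ^ vp) | X;
      uint64_t HP = vn | ~(D0 | vp);
      uint64_t HN = vp & D0;
      const uint64_t hb = (r == b - 1) ? last_hb : (1ULL << 63);
      int hout = (HP & hb) ? 1 : ((HN & hb) ? -1 : 0);
      HP <<= 1; HN <<= 1;
      if (hin > 0) HP |= 1ULL;
      if (hin < 0) HN |= 1ULL;
      VP[r] = HN | ~(D0 | HP);
      VN[r] = HP & D0;
      hin = hout;
    }
    score += hin;
    if (score < dmin) dmin = score;
    if (end_pos && score <= keep_max) end_pos->push_back(j);
  }
  return dmin;
}

// Simple unit-cost semi-global DP; exported for oracle tests of the Myers code.
static int edit_min_dp(const std::vector<int>& pat, const std::vector<int>& text) {
  const int m = (int)pat.size();
  std::vector<int> col(m + 1), ncol(m + 1);
  for (int i = 0; i <= m; ++i) col[i] = i;
  int dmin = m;
  for (size_t j = 0; j < text.size(); ++j) {
    ncol[0] = 0;
    for (int i = 1; i <= m; ++i) {
      int sub = col[i - 1] + ((pat[i - 1] < 4 && pat[i - 1] == text[j]) ? 0 : 1);
      int del = col[i] + 1;
      int ins = ncol[i - 1] + 1;
      ncol[i] = std::min(sub, std::min(del, ins));
    }
    std::swap(col, ncol);
    if (col[m] < dmin) dmin = col[m];
  }
  return dmin;
}

// ---------------------------------------------------------------------------
// Exported: pairwise glocal identity (shorter sequence end-to-end in longer).
// Equal-length pairs are evaluated in both roles and the lexicographically
// better alignment is reported, making the metric symmetric.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".pf_glocal_identity")]]
List pf_glocal_identity(std::string a, std::string b, bool rc_aware,
                        int match, int mismatch, int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  ScoreParams sp{match, mismatch, gap_open, gap_extend};
  std::vector<int> ea = encode(a), eb = encode(b);
  const bool a_pat = ea.size() <= eb.size();
  const bool b_pat = eb.size() <= ea.size();
  Tri best = tri_neg();
  bool reverse = false;
  // forward candidates first so ties resolve to forward orientation
  for (int strand = 0; strand < (rc_aware ? 2 : 1); ++strand) {
    for (int role = 0; role < 2; ++role) {
      if (role == 0 && !a_pat) continue; // a must be the shorter (or equal)
      if (role == 1 && !b_pat) continue; // b as pattern: equal length or shorter
      const std::vector<int>& pat0 = (role == 0) ? ea : eb;
      const std::vector<int>& sub0 = (role == 0) ? eb : ea;
      std::vector<int> patrc;
      const std::vector<int>* pat = &pat0;
      if (strand == 1) { patrc = revcomp_enc(pat0); pat = &patrc; }
      Tri t = glocal_align(pat->data(), (int)pat->size(),
                           sub0.data(), (int)sub0.size(), sp);
      if (tri_less(best, t)) { best = t; reverse = (strand == 1); }
    }
  }
  double identity = (best.cols > 0) ? (double)best.mt / (double)best.cols : 0.0;
  return List::create(_["identity"] = identity,
                      _["orientation"] = reverse ? "reverse" : "forward",
                      _["score"] = best.s,
                      _["matches"] = best.mt,
                      _["columns"] = best.cols);
}

// [[Rcpp::export(name = ".pf_local_identity")]]
List pf_local_identity(std::string a, std::string b, bool rc_aware,
                       int match, int mismatch, int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  ScoreParams sp{match, mismatch, gap_open, gap_extend};
  std::vector<int> ea = encode(a), eb = encode(b);
  Tri fwd = local_align(ea, eb, sp);
  bool reverse = false;
  Tri best = fwd;
  if (rc_aware) {
    std::vector<int> earc = revcomp_enc(ea);
    Tri rev = local_align(earc, eb, sp);
    if (tri_less(fwd, rev)) { best = rev; reverse = true; }
  }
  double identity = (best.cols > 0) ? (double)best.mt / (double)best.cols : 0.0;
  return List::create(_["identity"] = identity,
                      _["orientation"] = reverse ? "reverse" : "forward",
                      _["score"] = best.s,
                      _["matches"] = best.mt,
                      _["columns"] = best.cols);
}

// [[Rcpp::export(name = ".pf_myers_min")]]
int pf_myers_min(std::string pattern, std::string text) {
  if (pattern.empty()) return 0;
  std::vector<int> p = encode(pattern), t = encode(text);
  MyersPattern mp;
  mp.build(p.data(), (int)p.size());
  return myers_scan(mp, t.data(), (int)t.size(), -1, nullptr);
}

// [[Rcpp::export(name = ".pf_edit_min_dp")]]
int pf_edit_min_dp(std::string pattern, std::string text) {
  std::vector<int> p = encode(pattern), t = encode(text);
  return edit_min_dp(p, t);
}

// ---------------------------------------------------------------------------
// Seed index (CSR over 2-bit seed hashes) for one strand of the parent.
// ---------------------------------------------------------------------------
struct SeedIndex {
  int s = 0;
  std::vector<int> starts; // size 4^s + 1
  std::vector<int> pos;    // parent positions, CSR
  void build(const std::vector<int>& seq, int seed_len) {
    s = seed_len;
    const size_t nb = (size_t)1 << (2 * s);
    starts.assign(nb + 1, 0);
    const int n = (int)seq.size();
    uint32_t h = 0, mask = (uint32_t)(nb - 1);
    std::vector<std::pair<uint32_t, int>> kv; // (hash, seed start)
    kv.reserve(std::max(0, n - s + 1));
    int run = 0; // valid (non-N) run length
    for (int i = 0; i < n; ++i) {
      if (seq[i] >= 4) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint32_t)seq[i]) & mask;
      if (++run >= s) kv.push_back(std::make_pair(h, i - s + 1));
    }
    for (size_t j = 0; j < kv.size(); ++j) starts[kv[j].first + 1]++;
    for (size_t bkt = 1; bkt <= nb; ++bkt) starts[bkt] += starts[bkt - 1];
    pos.assign(kv.size(), 0);
    std::vector<int> fill(starts.begin(), starts.end() - 1);
    for (size_t j = 0; j < kv.size(); ++j) pos[fill[kv[j].first]++] = kv[j].second;
  }
};

// Rolling seed hashes of a query sequence; UINT32_MAX marks seeds containing N.
static std::vector<uint32_t> query_seed_hashes(const std::vector<int>& seq, int s) {
  const int n = (int)seq.size();
  std::vector<uint32_t> out(std::max(0, n - s + 1), UINT32_MAX);
  uint32_t h = 0, mask = (uint32_t)(((uint64_t)1 << (2 * s)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    if (seq[i] >= 4) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint32_t)seq[i]) & mask;
    if (++run >= s && i - s + 1 < (int)out.size()) out[i - s + 1] = h;
  }
  return out;
}

struct Region { int lo, hi; }; // half-open subject window

// Collect candidate parent regions for a query via exact seed hits.
// q-gram filter: a placement with <= d_hi unit edits retains at least
// (k - s + 1) - s*d_hi of the query's s-grams, and every retained s-gram's
// implied placement start lies within d_hi of the true start, i.e. inside one
// diagonal group.  Groups with fewer supporting seeds are provably outside
// the edit-distance bound and are skipped.
static void seed_regions(const std::vector<uint32_t>& qhash, int q_from, int q_to,
                         const SeedIndex& idx, int k, int pad, int sub_len,
                         int min_support,
                         std::vector<int>& starts_buf, std::vector<Region>& out) {
  starts_buf.clear();
  for (int q = q_from; q <= q_to; ++q) {
    uint32_t h = qhash[q];
    if (h == UINT32_MAX) continue;
    int b0 = idx.starts[h], b1 = idx.starts[h + 1];
    for (int t = b0; t < b1; ++t)
      starts_buf.push_back(idx.pos[t] - (q - q_from));
  }
  if (starts_buf.empty()) return;
  std::sort(starts_buf.begin(), starts_buf.end());
  const int gap = 2 * pad;
  int glo = starts_buf[0], ghi = starts_buf[0];
  int support = 1;
  for (size_t i = 1; i <= starts_buf.size(); ++i) {
    if (i < starts_buf.size() && starts_buf[i] - ghi <= gap) {
      ghi = starts_buf[i]; ++support; continue;
    }
    if (support >= min_support) {
      int lo = std::max(0, glo - pad);
      int hi = std::min(sub_len, ghi + k + pad);
      if (hi > lo) out.push_back(Region{lo, hi});
    }
    if (i < starts_buf.size()) { glo = starts_buf[i]; ghi = starts_buf[i]; support = 1; }
  }
}

// Classification of one query's candidate regions against one subject strand.
// mp must already hold the query.  Returns true if identity >= threshold.
static bool classify_regions(MyersPattern& mp, const int* query, int k,
                             const std::vector<int>& subject,
                             const std::vector<Region>& regions,
                             double threshold, int d_lo, int d_hi,
                             const ScoreParams& sp, std::vector<int>& ends_buf) {
  for (size_t r = 0; r < regions.size(); ++r) {
    const int* reg = subject.data() + regions[r].lo;
    const int rlen = regions[r].hi - regions[r].lo;
    if (rlen > 3 * k) {
      // very wide merged region: locate candidate ends first, then shrink
      ends_buf.clear();
      myers_scan(mp, reg, rlen, d_hi, &ends_buf);
      if (ends_buf.empty()) continue;
      for (size_t e = 0; e < ends_buf.size();) {
        size_t e2 = e;
        while (e2 + 1 < ends_buf.size() && ends_buf[e2 + 1] - ends_buf[e2] <= 2 * d_hi) ++e2;
        int lo = std::max(0, ends_buf[e] - k - d_hi - 2);
        int hi = std::min(rlen, ends_buf[e2] + d_hi + 2);
        int d = myers_scan(mp, reg + lo, hi - lo, -1, nullptr);
        if (d <= d_lo) return true;
        if (d <= d_hi) {
          Tri t = glocal_align(query, k, reg + lo, hi - lo, sp);
          if ((double)t.mt >= threshold * (double)t.cols - 1e-9) return true;
        }
        e = e2 + 1;
      }
      continue;
    }
    int d = myers_scan(mp, reg, rlen, -1, nullptr);
    if (d <= d_lo) return true;
    if (d <= d_hi) {
      Tri t = glocal_align(query, k, reg, rlen, sp);
      if ((double)t.mt >= threshold * (double)t.cols - 1e-9) return true;
    }
  }
  return false;
}

static int seed_len_for(int k, double threshold) {
  int d_hi = (int)std::floor((double)k * (1.0 - threshold) / threshold + 1e-9);
  int s = (k - d_hi) / (d_hi + 1);
  if (s > 12) s = 12;
  return s;
}

// ---------------------------------------------------------------------------
// Exported: classify every k-mer of a neighbor sequence against a parent.
// Returns an integer vector over offsets 0, step, 2*step, ...:
// 1 = represented (best glocal identity >= threshold), 0 = divergent.
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".pf_classify_kmers")]]
IntegerVector pf_classify_kmers(std::string neighbor, std::string parent,
                                int k, int step, double threshold, bool rc_aware,
                                int match, int mismatch, int gap_open, int gap_extend) {
  ScoreParams sp{match, mismatch, gap_open, gap_extend};
  std::vector<int> nb = encode(neighbor), pa = encode(parent), parc = revcomp_enc(pa);
  const int L = (int)nb.size();
  if (L < k) return IntegerVector(0);
  const int n_kmers = (L - k) / step + 1;
  IntegerVector out(n_kmers);

  int d_hi = (int)std::floor((double)k * (1.0 - threshold) / threshold + 1e-9);
  int d_lo = (int)std::floor((double)k * (1.0 - threshold) / (1.0 + threshold) + 1e-9);
  int s = seed_len_for(k, threshold);
  const int pad = d_hi + 2;

  MyersPattern mp;
  std::vector<int> starts_buf, ends_buf;
  std::vector<Region> regs;

  if (s >= 4) {
    SeedIndex ixf, ixr;
    ixf.build(pa, s);
    if (rc_aware) ixr.build(parc, s);
    std::vector<uint32_t> qhash = query_seed_hashes(nb, s);
    const int min_support = std::max(1, (k - s + 1) - s * d_hi);
    for (int t = 0; t < n_kmers; ++t) {
      const int off = t * step;
      const int* query = nb.data() + off;
      mp.build(query, k);
      const int q_to = off + k - s;
      bool rep = false;
      regs.clear();
      seed_regions(qhash, off, q_to, ixf, k, pad, (int)pa.size(), min_support,
                   starts_buf, regs);
      if (!regs.empty())
        rep = classify_regions(mp, query, k, pa, regs, threshold, d_lo, d_hi, sp, ends_buf);
      if (!rep && rc_aware) {
        regs.clear();
        seed_regions(qhash, off, q_to, ixr, k, pad, (int)parc.size(), min_support,
                     starts_buf, regs);
        if (!regs.empty())
          rep = classify_regions(mp, query, k, parc, regs, threshold, d_lo, d_hi, sp, ends_buf);
      }
      out[t] = rep ? 1 : 0;
    }
  } else {
    // threshold too permissive for pigeonhole seeding: full-text scan
    std::vector<Region> whole_f(1, Region{0, (int)pa.size()});
    std::vector<Region> whole_r(1, Region{0, (int)parc.size()});
    for (int t = 0; t < n_kmers; ++t) {
      const int off = t * step;
      const int* query = nb.data() + off;
      mp.build(query, k);
      bool rep = classify_regions(mp, query, k, pa, whole_f, threshold, d_lo, d_hi, sp, ends_buf);
      if (!rep && rc_aware)
        rep = classify_regions(mp, query, k, parc, whole_r, threshold, d_lo, d_hi, sp, ends_buf);
      out[t] = rep ? 1 : 0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exported: best glocal placement of a query anywhere in a subject, exact with
// respect to the threshold decision (used by the host-similarity filter).
// Returns hit flag and the best identity computed among candidate placements
// (-1 when no placement reached the edit-distance feasibility bound).
// ---------------------------------------------------------------------------
// [[Rcpp::export(name = ".pf_best_glocal_hit")]]
List pf_best_glocal_hit(std::string query, std::string subject, double threshold,
                        bool rc_aware,
                        int match, int mismatch, int gap_open, int gap_extend) {
  ScoreParams sp{match, mismatch, gap_open, gap_extend};
  std::vector<int> q = encode(query), su = encode(subject);
  const int k = (int)q.size();
  int d_hi = (int)std::floor((double)k * (1.0 - threshold) / threshold + 1e-9);
  double best_id = -1.0;
  bool hit = false;
  MyersPattern mp;
  mp.build(q.data(), k);
  for (int strand = 0; strand < (rc_aware ? 2 : 1); ++strand) {
    std::vector<int> sub = (strand == 0) ? su : revcomp_enc(su);
    std::vector<int> ends;
    myers_scan(mp, sub.data(), (int)sub.size(), d_hi, &ends);
    for (size_t e = 0; e < ends.size();) {
      size_t e2 = e;
      while (e2 + 1 < ends.size() && ends[e2 + 1] - ends[e2] <= 2 * d_hi) ++e2;
      int lo = std::max(0, ends[e] - k - d_hi - 2);
      int hi = std::min((int)sub.size(), ends[e2] + d_hi + 2);
      Tri t = glocal_align(q.data(), k, sub.data() + lo, hi - lo, sp);
      double id = (t.cols > 0) ? (double)t.mt / (double)t.cols : 0.0;
      if (id > best_id) best_id = id;
      if ((double)t.mt >= threshold * (double)t.cols - 1e-9) hit = true;
      e = e2 + 1;
    }
    if (hit) break;
  }
  return List::create(_["hit"] = hit, _["identity"] = best_id);
}
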