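// Self-contained alignment engine: k-mer index, banded affine-gap
// Smith-Waterman with traceback, seed-and-extend read mapping, BLAST-like
// local search, k-mer dot plots and pileup polishing.
//
// Conventions shared with the R layer:
//  - all coordinates 0-based, half-open;
//  - gap of length L costs gap_open + L * gap_ext (first gapped base pays
//    both), matching Biostrings::pairwiseAlignment;
//  - identity = matches / alignment columns (M + I + D);
//  - CIGAR ops: M (align), I (insertion in query), D (deletion from query),
//    S (soft clip, query ends only).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>
#include <map>

using namespace Rcpp;

static const int NEG_INF = -100000000;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

struct Scoring {
  int match, mism, gopen, gext;
};

struct AlnRes {
  bool ok = false;
  int score = 0;
  int qs = 0, qe = 0;   // aligned query interval [qs, qe)
  int rs = 0, re = 0;   // aligned reference interval [rs, re)
  int matches = 0, cols = 0;
  std::string cigar;    // includes terminal soft clips
};

static void append_op(std::string& cig, int len, char op) {
  if (len <= 0) return;
  cig += std::to_string(len);
  cig += op;
}

// Banded local alignment of q vs r around diagonal d0 (ref_pos - query_pos).
// Traceback byte: bits 0-1 H source (0 stop, 1 diag, 2 E/horizontal=D,
// 3 F/vertical=I); bit 2 E extended; bit 3 F extended.
static AlnRes banded_local(const char* q, int m, const char* r, int n,
                           int d0, int band, const Scoring& sc) {
  AlnRes res;
  if (m <= 0 || n <= 0) return res;
  const int W = 2 * band + 1;
  std::vector<int> Hprev(n + 2, 0), Hcur(n + 2, 0);
  std::vector<int> Fcol(n + 2, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);

  int best = 0, bi = -1, bj = -1;
  // row 0 is all zeros (local)
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + d0 - band);
    int jhi = std::min(n, i + d0 + band);
    std::fill(Hcur.begin(), Hcur.end(), 0);
    if (jlo > jhi) continue;
    int E = NEG_INF;
    // cell just left of the band starts a fresh E
    for (int j = jlo; j <= jhi; ++j) {
      uint8_t t = 0;
      // E: gap in query (consumes ref)
      int e_open = (j - 1 >= jlo - 1 ? Hcur[j - 1] : 0) - sc.gopen - sc.gext;
      if (j - 1 < jlo) e_open = NEG_INF;          // left neighbour outside band
      int e_ext = E - sc.gext;
      if (e_ext >= e_open) { E = e_ext; t |= 4; } else { E = e_open; }
      // F: gap in ref (consumes query)
      int up_in_band = (j >= (i - 1) + d0 - band && j <= (i - 1) + d0 + band);
      int f_open = (up_in_band ? Hprev[j] : NEG_INF) - sc.gopen - sc.gext;
      int f_ext = Fcol[j] - sc.gext;
      int F;
      if (f_ext >= f_open) { F = f_ext; t |= 8; } else { F = f_open; }
      Fcol[j] = F;
      // H
      int diag_in_band = (j - 1 >= (i - 1) + d0 - band && j - 1 <= (i - 1) + d0 + band);
      int sub = (base2bit(q[i - 1]) == base2bit(r[j - 1]) &&
                 base2bit(q[i - 1]) >= 0) ? sc.match : sc.mism;
      int hdiag = (diag_in_band ? Hprev[j - 1] : (i == 1 || j == 1 ? 0 : NEG_INF)) + sub;
      int h = 0; uint8_t src = 0;
      if (hdiag > h) { h = hdiag; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }
      Hcur[j] = h;
      t |= src;
      tb[(size_t)i * W + (j - (i + d0 - band))] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return res;

  // traceback
  std::string ops;
  int i = bi, j = bj;
  int matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * W + (j - (i + d0 - band))];
    uint8_t src = t & 3;
    if (src == 0) break;
    if (src == 1) {
      ops += 'M'; ++cols;
      if (base2bit(q[i - 1]) == base2bit(r[j - 1])) ++matches;
      --i; --j;
    } else if (src == 2) {
      while (true) {
        ops += 'D'; ++cols;
        uint8_t tt = tb[(size_t)i * W + (j - (i + d0 - band))];
        --j;
        if (!(tt & 4)) break;
        if (j <= 0) break;
      }
    } else {
      while (true) {
        ops += 'I'; ++cols;
        uint8_t tt = tb[(size_t)i * W + (j - (i + d0 - band))];
        --i;
        if (!(tt & 8)) break;
        if (i <= 0) break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  res.ok = true;
  res.score = best;
  res.qs = i; res.qe = bi;
  res.rs = j; res.re = bj;
  res.matches = matches; res.cols = cols;
  // run-length encode with soft clips
  std::string cig;
  append_op(cig, res.qs, 'S');
  int run = 0; char cur = 0;
  for (char o : ops) {
    if (o == cur) ++run;
    else { append_op(cig, run, cur ? cur : 'M'); cur = o; run = 1; }
  }
  append_op(cig, run, cur);
  append_op(cig, m - res.qe, 'S');
  res.cigar = cig;
  return res;
}

// Full-matrix optimal local alignment (oracle-grade, small inputs).
static AlnRes full_local(const std::string& q, const std::string& r,
                         const Scoring& sc) {
  int m = q.size(), n = r.size();
  if ((double)m * (double)n > 6.4e7)
    stop("sequences too long for full-matrix alignment");
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= m; ++i) {
    int E = NEG_INF;
    Hcur[0] = 0;
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      int e_open = Hcur[j - 1] - sc.gopen - sc.gext;
      int e_ext = E - sc.gext;
      if (e_ext >= e_open) { E = e_ext; t |= 4; } else E = e_open;
      int f_open = Hprev[j] - sc.gopen - sc.gext;
      int f_ext = Fcol[j] - sc.gext;
      int F;
      if (f_ext >= f_open) { F = f_ext; t |= 8; } else F = f_open;
      Fcol[j] = F;
      int sub = (base2bit(q[i - 1]) == base2bit(r[j - 1]) &&
                 base2bit(q[i - 1]) >= 0) ? sc.match : sc.mism;
      int h = 0; uint8_t src = 0;
      int hd = Hprev[j - 1] + sub;
      if (hd > h) { h = hd; src = 1; }
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }
      Hcur[j] = h; t |= src;
      tb[(size_t)i * (n + 1) + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  AlnRes res;
  if (best <= 0) return res;
  std::string ops;
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    uint8_t src = t & 3;
    if (src == 0) break;
    if (src == 1) {
      ops += 'M'; ++cols;
      if (base2bit(q[i - 1]) == base2bit(r[j - 1])) ++matches;
      --i; --j;
    } else if (src == 2) {
      while (true) {
        ops += 'D'; ++cols;
        uint8_t tt = tb[(size_t)i * (n + 1) + j];
        --j;
        if (!(tt & 4) || j <= 0) break;
      }
    } else {
      while (true) {
        ops += 'I'; ++cols;
        uint8_t tt = tb[(size_t)i * (n + 1) + j];
        --i;
        if (!(tt & 8) || i <= 0) break;
      }
    }
  }
  std::reverse(ops.begin(), ops.end());
  res.ok = true; res.score = best;
  res.qs = i; res.qe = bi; res.rs = j; res.re = bj;
  res.matches = matches; res.cols = cols;
  std::string cig;
  append_op(cig, res.qs, 'S');
  int run = 0; char cur = 0;
  for (char o : ops) {
    if (o == cur) ++run;
    else { append_op(cig, run, cur ? cur : 'M'); cur = o; run = 1; }
  }
  append_op(cig, run, cur);
  append_op(cig, m - res.qe, 'S');
  res.cigar = cig;
  return res;
}

// [[Rcpp::export]]
List cpp_sw(std::string a, std::string b, int match, int mism,
            int gopen, int gext) {
  Scoring sc{match, mism, gopen, gext};
  AlnRes r = full_local(a, b, sc);
  return List::create(
    _["score"] = r.ok ? r.score : 0,
    _["a_start"] = r.qs, _["a_end"] = r.qe,
    _["b_start"] = r.rs, _["b_end"] = r.re,
    _["matches"] = r.matches, _["aln_length"] = r.cols,
    _["identity"] = r.cols > 0 ? (double)r.matches / r.cols : NA_REAL,
    _["cigar"] = r.cigar);
}

// [[Rcpp::export]]
List cpp_align_hint(std::string a, std::string b, int diag, int band,
                    int match, int mism, int gopen, int gext) {
  Scoring sc{match, mism, gopen, gext};
  AlnRes r = banded_local(a.c_str(), a.size(), b.c_str(), b.size(),
                          diag, band, sc);
  return List::create(
    _["score"] = r.ok ? r.score : 0,
    _["a_start"] = r.qs, _["a_end"] = r.qe,
    _["b_start"] = r.rs, _["b_end"] = r.re,
    _["matches"] = r.matches, _["aln_length"] = r.cols,
    _["identity"] = r.cols > 0 ? (double)r.matches / r.cols : NA_REAL,
    _["cigar"] = r.cigar);
}

// Global (end-to-end) affine alignment, for pairwise identity of repeat
// copies and consensus-vs-truth comparisons.
// [[Rcpp::export]]
List cpp_nw(std::string a, std::string b, int match, int mism,
            int gopen, int gext) {
  int m = a.size(), n = b.size();
  if (m == 0 || n == 0) stop("empty sequence");
  if ((double)m * (double)n > 6.4e7) stop("sequences too long");
  Scoring sc{match, mism, gopen, gext};
  std::vector<int> Hprev(n + 1), Hcur(n + 1), Fcol(n + 1, NEG_INF);
  std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
  Hprev[0] = 0;
  for (int j = 1; j <= n; ++j) {
    Hprev[j] = -sc.gopen - j * sc.gext;
    tb[j] = 2 | 4;
  }
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = -sc.gopen - i * sc.gext;
    tb[(size_t)i * (n + 1)] = 3 | 8;
    int E = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      uint8_t t = 0;
      int e_open = Hcur[j - 1] - sc.gopen - sc.gext;
      int e_ext = E - sc.gext;
      if (e_ext >= e_open) { E = e_ext; t |= 4; } else E = e_open;
      int f_open = Hprev[j] - sc.gopen - sc.gext;
      int f_ext = Fcol[j] - sc.gext;
      int F;
      if (f_ext >= f_open) { F = f_ext; t |= 8; } else F = f_open;
      Fcol[j] = F;
      int sub = (base2bit(a[i - 1]) == base2bit(b[j - 1]) &&
                 base2bit(a[i - 1]) >= 0) ? sc.match : sc.mism;
      int h = Hprev[j - 1] + sub; uint8_t src = 1;
      if (E > h) { h = E; src = 2; }
      if (F > h) { h = F; src = 3; }
      Hcur[j] = h; t |= src;
      tb[(size_t)i * (n + 1) + j] = t;
    }
    std::swap(Hprev, Hcur);
  }
  int score = Hprev[n];
  int i = m, j = n, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    uint8_t t = tb[(size_t)i * (n + 1) + j];
    uint8_t src = t & 3;
    if (i > 0 && j > 0 && src == 1) {
      ++cols;
      if (base2bit(a[i - 1]) == base2bit(b[j - 1])) ++matches;
      --i; --j;
    } else if (j > 0 && (src == 2 || i == 0)) {
      while (j > 0) {
        ++cols;
        uint8_t tt = tb[(size_t)i * (n + 1) + j];
        --j;
        if (!(tt & 4) || j == 0) break;
      }
    } else {
      while (i > 0) {
        ++cols;
        uint8_t tt = tb[(size_t)i * (n + 1) + j];
        --i;
        if (!(tt & 8) || i == 0) break;
      }
    }
  }
  return List::create(
    _["score"] = score,
    _["matches"] = matches, _["aln_length"] = cols,
    _["identity"] = cols > 0 ? (double)matches / cols : NA_REAL);
}

// ---------------------------------------------------------------------------
// k-mer index

struct KIndex {
  int k = 15;
  int max_occ = 256;
  std::vector<std::string> names, seqs;
  std::unordered_map<uint64_t, std::vector<uint64_t>> pos; // (ref<<40)|pos
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs,
                     int k, int max_occ) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  KIndex* idx = new KIndex();
  idx->k = k; idx->max_occ = max_occ;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (int s = 0; s < names.size(); ++s) {
    idx->names.push_back(as<std::string>(names[s]));
    idx->seqs.push_back(as<std::string>(seqs[s]));
    const std::string& sq = idx->seqs.back();
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < sq.size(); ++p) {
      int b = base2bit(sq[p]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        idx->pos[kmer].push_back(((uint64_t)s << 40) | (uint64_t)(p - k + 1));
    }
  }
  XPtr<KIndex> xp(idx, true);
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp_) {
  XPtr<KIndex> xp(xp_);
  size_t npos = 0;
  for (auto& kv : xp->pos) npos += kv.second.size();
  return List::create(_["k"] = xp->k, _["n_ref"] = (int)xp->names.size(),
                      _["n_kmers"] = (double)xp->pos.size(),
                      _["n_positions"] = (double)npos,
                      _["ref_names"] = wrap(xp->names));
}

// [[Rcpp::export]]
List cpp_query_kmer(SEXP xp_, std::string kmer) {
  XPtr<KIndex> xp(xp_);
  if ((int)kmer.size() != xp->k) stop("kmer length must equal index k");
  uint64_t v = 0;
  for (char c : kmer) {
    int b = base2bit(c);
    if (b < 0) stop("non-ACGT base in kmer");
    v = (v << 2) | (uint64_t)b;
  }
  auto it = xp->pos.find(v);
  std::vector<int> refs, starts;
  if (it != xp->pos.end()) {
    for (uint64_t p : it->second) {
      refs.push_back((int)(p >> 40) + 1);
      starts.push_back((int)(p & 0xFFFFFFFFFFULL));
    }
  }
  return List::create(_["ref"] = wrap(refs), _["pos"] = wrap(starts));
}

struct Seed { int ref; int strand; long diag; int qpos; long rpos; };

struct Cluster {
  int ref, strand, count;
  long dmin, dmax, rmin, rmax;
  int qmin, qmax;
};

static void collect_seeds(const KIndex& idx, const std::string& s, int strand,
                          int step, std::vector<Seed>& seeds) {
  int k = idx.k;
  int L = s.size();
  if (L < k) return;
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  uint64_t kmer = 0; int run = 0;
  for (int p = 0; p < L; ++p) {
    int b = base2bit(s[p]);
    if (b < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)b) & mask;
    if (++run >= k) {
      int qpos = p - k + 1;
      if (qpos % step != 0) continue;
      auto it = idx.pos.find(kmer);
      if (it == idx.pos.end()) continue;
      if ((int)it->second.size() > idx.max_occ) continue;
      for (uint64_t pk : it->second) {
        int ref = (int)(pk >> 40);
        long rpos = (long)(pk & 0xFFFFFFFFFFULL);
        seeds.push_back({ref, strand, rpos - qpos, qpos, rpos});
      }
    }
  }
}

static std::vector<Cluster> cluster_seeds(std::vector<Seed>& seeds,
                                          long diag_tol, long chain_gap) {
  std::vector<Cluster> cl;
  if (seeds.empty()) return cl;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.strand != b.strand) return a.strand < b.strand;
    if (a.diag != b.diag) return a.diag < b.diag;
    return a.qpos < b.qpos;
  });
  for (const Seed& s : seeds) {
    if (!cl.empty()) {
      Cluster& c = cl.back();
      if (c.ref == s.ref && c.strand == s.strand && s.diag - c.dmax <= diag_tol) {
        c.count++;
        c.dmax = s.diag;
        c.rmin = std::min(c.rmin, s.rpos); c.rmax = std::max(c.rmax, s.rpos);
        c.qmin = std::min(c.qmin, s.qpos); c.qmax = std::max(c.qmax, s.qpos);
        continue;
      }
    }
    cl.push_back({s.ref, s.strand, 1, s.diag, s.diag, s.rpos, s.rpos,
                  s.qpos, s.qpos});
  }
  // chain clusters that sit on nearby diagonals within a positional gap
  if (chain_gap > 0 && cl.size() > 1) {
    std::sort(cl.begin(), cl.end(), [](const Cluster& a, const Cluster& b) {
      if (a.ref != b.ref) return a.ref < b.ref;
      if (a.strand != b.strand) return a.strand < b.strand;
      return a.rmin < b.rmin;
    });
    std::vector<Cluster> merged;
    for (const Cluster& c : cl) {
      if (!merged.empty()) {
        Cluster& p = merged.back();
        bool near_diag = !(c.dmin > p.dmax + diag_tol || p.dmin > c.dmax + diag_tol);
        if (p.ref == c.ref && p.strand == c.strand && near_diag &&
            c.rmin <= p.rmax + chain_gap) {
          p.count += c.count;
          p.dmin = std::min(p.dmin, c.dmin); p.dmax = std::max(p.dmax, c.dmax);
          p.rmin = std::min(p.rmin, c.rmin); p.rmax = std::max(p.rmax, c.rmax);
          p.qmin = std::min(p.qmin, c.qmin); p.qmax = std::max(p.qmax, c.qmax);
          continue;
        }
      }
      merged.push_back(c);
    }
    cl.swap(merged);
  }
  return cl;
}

struct Hit {
  int ref, strand;
  long rs, re;
  int qs, qe;
  int score, matches, cols;
  std::string cigar;
};

static bool extend_cluster(const KIndex& idx, const std::string& s,
                           const Cluster& c, int band, const Scoring& sc,
                           Hit& out) {
  const std::string& ref = idx.seqs[c.ref];
  int k = idx.k;
  int L = s.size();
  long ws = std::max(0L, c.rmin - (long)c.qmin - band - 8);
  long we = std::min((long)ref.size(),
                     c.rmax + k + (long)(L - c.qmax) + band + 8);
  if (we <= ws) return false;
  long dmid = (c.dmin + c.dmax) / 2;
  int d0 = (int)(dmid - ws);
  int ebnd = band + (int)((c.dmax - c.dmin) / 2 + 1);
  AlnRes r = banded_local(s.c_str(), L, ref.c_str() + ws, (int)(we - ws),
                          d0, ebnd, sc);
  if (!r.ok) return false;
  out.ref = c.ref; out.strand = c.strand;
  out.rs = ws + r.rs; out.re = ws + r.re;
  out.qs = r.qs; out.qe = r.qe;
  out.score = r.score; out.matches = r.matches; out.cols = r.cols;
  out.cigar = r.cigar;
  return true;
}

// Map a batch of reads; returns every locus tying the best score per read.
// [[Rcpp::export]]
DataFrame cpp_map_reads(SEXP xp_, CharacterVector reads, CharacterVector ids,
                        int match, int mism, int gopen, int gext,
                        int band, int min_seeds, int max_loci, int seed_step) {
  XPtr<KIndex> xp(xp_);
  Scoring sc{match, mism, gopen, gext};
  std::vector<std::string> o_id, o_ref, o_cigar;
  std::vector<int> o_strand, o_start, o_end, o_score, o_alen, o_nbest,
                   o_mapq, o_qs, o_qe;
  std::vector<double> o_ident;

  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    std::string rev = revcomp(fwd);
    int L = fwd.size();
    if (L < xp->k) continue;
    int step = seed_step > 0 ? seed_step : (L <= 500 ? 1 : 3);
    std::vector<Seed> seeds;
    collect_seeds(*xp, fwd, 0, step, seeds);
    collect_seeds(*xp, rev, 1, step, seeds);
    std::vector<Cluster> cl = cluster_seeds(seeds, band, 0);
    cl.erase(std::remove_if(cl.begin(), cl.end(), [&](const Cluster& c) {
      return c.count < min_seeds;
    }), cl.end());
    if (cl.empty()) continue;
    std::sort(cl.begin(), cl.end(), [](const Cluster& a, const Cluster& b) {
      return a.count > b.count;
    });
    if ((int)cl.size() > max_loci) cl.resize(max_loci);
    std::vector<Hit> hits;
    for (const Cluster& c : cl) {
      Hit h;
      if (extend_cluster(*xp, c.strand == 0 ? fwd : rev, c, band, sc, h))
        hits.push_back(h);
    }
    if (hits.empty()) continue;
    int best = 0;
    for (const Hit& h : hits) best = std::max(best, h.score);
    // keep ties, dedup by (ref, start)
    std::vector<Hit> kept;
    for (const Hit& h : hits) {
      if (h.score != best) continue;
      bool dup = false;
      for (const Hit& u : kept)
        if (u.ref == h.ref && std::labs(u.rs - h.rs) < 5) { dup = true; break; }
      if (!dup) kept.push_back(h);
    }
    std::sort(kept.begin(), kept.end(), [&](const Hit& a, const Hit& b) {
      if (a.ref != b.ref) return xp->names[a.ref] < xp->names[b.ref];
      return a.rs < b.rs;
    });
    int nb = kept.size();
    int mq = nb == 1 ? 40 : 0;
    for (const Hit& h : kept) {
      o_id.push_back(as<std::string>(ids[ri]));
      o_ref.push_back(xp->names[h.ref]);
      o_strand.push_back(h.strand);
      o_start.push_back((int)h.rs);
      o_end.push_back((int)h.re);
      o_cigar.push_back(h.cigar);
      o_score.push_back(h.score);
      o_ident.push_back(h.cols > 0 ? (double)h.matches / h.cols : NA_REAL);
      o_alen.push_back(h.cols);
      o_nbest.push_back(nb);
      o_mapq.push_back(mq);
      o_qs.push_back(h.qs);
      o_qe.push_back(h.qe);
    }
  }
  return DataFrame::create(
    _["read_id"] = o_id, _["ref"] = o_ref, _["strand"] = o_strand,
    _["start"] = o_start, _["end"] = o_end, _["cigar"] = o_cigar,
    _["score"] = o_score, _["identity"] = o_ident, _["aln_length"] = o_alen,
    _["n_best"] = o_nbest, _["mapq"] = o_mapq,
    _["qstart"] = o_qs, _["qend"] = o_qe,
    _["stringsAsFactors"] = false);
}

// BLAST-like local search: all loci above min_score, not just the best.
// [[Rcpp::export]]
DataFrame cpp_local_search(SEXP xp_, std::string query,
                           int match, int mism, int gopen, int gext,
                           int band, int min_score, int min_seeds,
                           int max_loci, int seed_step, int chain_gap) {
  XPtr<KIndex> xp(xp_);
  Scoring sc{match, mism, gopen, gext};
  int L = query.size();
  std::string rev = revcomp(query);
  int step = seed_step > 0 ? seed_step : (L <= 2000 ? 1 : 2);
  std::vector<Seed> seeds;
  collect_seeds(*xp, query, 0, step, seeds);
  collect_seeds(*xp, rev, 1, step, seeds);
  std::vector<Cluster> cl = cluster_seeds(seeds, band, chain_gap);
  cl.erase(std::remove_if(cl.begin(), cl.end(), [&](const Cluster& c) {
    return c.count < min_seeds;
  }), cl.end());
  std::sort(cl.begin(), cl.end(), [](const Cluster& a, const Cluster& b) {
    return a.count > b.count;
  });
  if ((int)cl.size() > max_loci) cl.resize(max_loci);
  std::vector<Hit> hits;
  for (const Cluster& c : cl) {
    Hit h;
    if (extend_cluster(*xp, c.strand == 0 ? query : rev, c, band, sc, h) &&
        h.score >= min_score)
      hits.push_back(h);
  }
  // drop hits mostly contained in a better hit on the same reference
  std::sort(hits.begin(), hits.end(), [](const Hit& a, const Hit& b) {
    return a.score > b.score;
  });
  std::vector<Hit> kept;
  for (const Hit& h : hits) {
    bool shadowed = false;
    for (const Hit& u : kept) {
      if (u.ref != h.ref) continue;
      long ov = std::min(u.re, h.re) - std::max(u.rs, h.rs);
      long len = h.re - h.rs;
      if (len > 0 && ov > 0 && (double)ov / len > 0.5) { shadowed = true; break; }
    }
    if (!shadowed) kept.push_back(h);
  }
  // sort: score desc, ties by (ref name, start)
  std::sort(kept.begin(), kept.end(), [&](const Hit& a, const Hit& b) {
    if (a.score != b.score) return a.score > b.score;
    if (xp->names[a.ref] != xp->names[b.ref])
      return xp->names[a.ref] < xp->names[b.ref];
    return a.rs < b.rs;
  });
  std::vector<std::string> o_ref;
  std::vector<int> o_strand, o_rs, o_re, o_qs, o_qe, o_score, o_alen;
  std::vector<double> o_ident;
  for (const Hit& h : kept) {
    o_ref.push_back(xp->names[h.ref]);
    o_strand.push_back(h.strand);
    o_rs.push_back((int)h.rs); o_re.push_back((int)h.re);
    // report query coords on the forward query orientation
    if (h.strand == 0) { o_qs.push_back(h.qs); o_qe.push_back(h.qe); }
    else { o_qs.push_back(L - h.qe); o_qe.push_back(L - h.qs); }
    o_score.push_back(h.score);
    o_ident.push_back(h.cols > 0 ? (double)h.matches / h.cols : NA_REAL);
    o_alen.push_back(h.cols);
  }
  return DataFrame::create(
    _["ref"] = o_ref, _["strand"] = o_strand,
    _["ref_start"] = o_rs, _["ref_end"] = o_re,
    _["qstart"] = o_qs, _["qend"] = o_qe,
    _["score"] = o_score, _["identity"] = o_ident,
    _["aln_length"] = o_alen, _["stringsAsFactors"] = false);
}

// All exact shared k-mers between two sequences (both orientations).
// [[Rcpp::export]]
DataFrame cpp_kmer_matches(std::string a, std::string b, int k) {
  if (k < 8 || k > 31) stop("k must be in [8, 31]");
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::unordered_map<uint64_t, std::vector<int>> amap;
  {
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < a.size(); ++p) {
      int bb = base2bit(a[p]);
      if (bb < 0) { run = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)bb) & mask;
      if (++run >= k) amap[kmer].push_back((int)(p - k + 1));
    }
  }
  std::vector<int> pa, pb; std::vector<std::string> strand;
  for (int so = 0; so < 2; ++so) {
    std::string s = so == 0 ? b : revcomp(b);
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int bb = base2bit(s[p]);
      if (bb < 0) { run = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)bb) & mask;
      if (++run >= k) {
        auto it = amap.find(kmer);
        if (it == amap.end()) continue;
        int q = (int)(p - k + 1);
        int bq = so == 0 ? q : (int)s.size() - k - q;
        for (int ap : it->second) {
          pa.push_back(ap); pb.push_back(bq);
          strand.push_back(so == 0 ? "+" : "-");
        }
      }
    }
  }
  return DataFrame::create(_["pos_a"] = pa, _["pos_b"] = pb,
                           _["strand"] = strand,
                           _["stringsAsFactors"] = false);
}

// Best shared-kmer diagonal between pre-oriented sequences (forward only).
// Returns diag (pos_a - pos_b) of the most populated 32-bp diagonal bin.
// [[Rcpp::export]]
List cpp_best_diag(std::string a, std::string b, int k) {
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::unordered_map<uint64_t, std::vector<int>> amap;
  {
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < a.size(); ++p) {
      int bb = base2bit(a[p]);
      if (bb < 0) { run = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)bb) & mask;
      if (++run >= k) amap[kmer].push_back((int)(p - k + 1));
    }
  }
  std::map<int, int> bins;
  uint64_t kmer = 0; int run = 0;
  for (size_t p = 0; p < b.size(); ++p) {
    int bb = base2bit(b[p]);
    if (bb < 0) { run = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)bb) & mask;
    if (++run >= k) {
      auto it = amap.find(kmer);
      if (it == amap.end()) continue;
      int q = (int)(p - k + 1);
      if ((int)it->second.size() > 64) continue;
      for (int ap : it->second) bins[(ap - q) / 32]++;
    }
  }
  if (bins.empty())
    return List::create(_["diag"] = NA_INTEGER, _["count"] = 0);
  int bestbin = 0, bestn = -1;
  for (auto& kv : bins) {
    int n = kv.second;
    auto lo = bins.find(kv.first - 1);
    auto hi = bins.find(kv.first + 1);
    if (lo != bins.end()) n += lo->second;
    if (hi != bins.end()) n += hi->second;
    if (n > bestn) { bestn = n; bestbin = kv.first; }
  }
  return List::create(_["diag"] = bestbin * 32 + 16, _["count"] = bestn);
}

// Top candidate diagonals (smoothed 32-bp bins, local maxima), best first.
// [[Rcpp::export]]
DataFrame cpp_best_diags(std::string a, std::string b, int k, int top) {
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  std::unordered_map<uint64_t, std::vector<int>> amap;
  {
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < a.size(); ++p) {
      int bb = base2bit(a[p]);
      if (bb < 0) { run = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)bb) & mask;
      if (++run >= k) amap[kmer].push_back((int)(p - k + 1));
    }
  }
  std::map<int, int> bins;
  uint64_t kmer = 0; int run = 0;
  for (size_t p = 0; p < b.size(); ++p) {
    int bb = base2bit(b[p]);
    if (bb < 0) { run = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)bb) & mask;
    if (++run >= k) {
      auto it = amap.find(kmer);
      if (it == amap.end()) continue;
      if ((int)it->second.size() > 64) continue;
      int q = (int)(p - k + 1);
      for (int ap : it->second) bins[(ap - q) / 32]++;
    }
  }
  std::vector<std::pair<int, int>> scored;  // (smoothed count, bin)
  for (auto& kv : bins) {
    int n = kv.second;
    auto lo = bins.find(kv.first - 1);
    auto hi = bins.find(kv.first + 1);
    if (lo != bins.end()) n += lo->second;
    if (hi != bins.end()) n += hi->second;
    scored.push_back({n, kv.first});
  }
  std::sort(scored.begin(), scored.end(),
            [](const std::pair<int,int>& x, const std::pair<int,int>& y) {
              return x.first > y.first;
            });
  std::vector<int> diags, counts;
  for (auto& s : scored) {
    bool close = false;
    for (int d : diags) if (std::abs(d - (s.second * 32 + 16)) < 96) close = true;
    if (close) continue;
    diags.push_back(s.second * 32 + 16);
    counts.push_back(s.first);
    if ((int)diags.size() >= top) break;
  }
  return DataFrame::create(_["diag"] = diags, _["count"] = counts);
}

// One round of majority-vote pileup polishing of a draft against its reads.
// Reads must already be oriented to the draft strand.
// [[Rcpp::export]]
List cpp_polish(std::string draft, CharacterVector reads, int k, int band,
                int match, int mism, int gopen, int gext) {
  int n = draft.size();
  Scoring sc{match, mism, gopen, gext};
  std::vector<std::array<int, 4>> bv(n, {0, 0, 0, 0});
  std::vector<int> delv(n, 0), cov(n, 0);
  std::map<int, std::map<std::string, int>> insv;
  int used = 0;
  for (int ri = 0; ri < reads.size(); ++ri) {
    std::string rd = as<std::string>(reads[ri]);
    List bd = cpp_best_diag(draft, rd, k);
    if (IntegerVector(bd["count"])[0] < 3) continue;
    int diag = IntegerVector(bd["diag"])[0];
    AlnRes r = banded_local(rd.c_str(), rd.size(), draft.c_str(), n,
                            diag, band, sc);
    if (!r.ok || r.cols < 200) continue;
    ++used;
    // walk cigar
    int qi = 0, dj = r.rs;
    size_t ci = 0;
    const std::string& cg = r.cigar;
    while (ci < cg.size()) {
      int len = 0;
      while (ci < cg.size() && cg[ci] >= '0' && cg[ci] <= '9')
        len = len * 10 + (cg[ci++] - '0');
      char op = cg[ci++];
      if (op == 'S') { qi += len; continue; }
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          int bb = base2bit(rd[qi]);
          if (bb >= 0 && dj < n) { bv[dj][bb]++; cov[dj]++; }
          ++qi; ++dj;
        }
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          if (dj < n) { delv[dj]++; cov[dj]++; }
          ++dj;
        }
      } else if (op == 'I') {
        if (dj < n) insv[dj][rd.substr(qi, len)]++;
        qi += len;
      }
    }
  }
  static const char* BASES = "ACGT";
  std::string out;
  out.reserve(n + n / 10);
  for (int j = 0; j < n; ++j) {
    auto it = insv.find(j);
    if (it != insv.end() && cov[j] > 0) {
      // best insertion before position j
      int bestc = 0; const std::string* bests = nullptr;
      for (auto& kv : it->second)
        if (kv.second > bestc) { bestc = kv.second; bests = &kv.first; }
      if (bests && 2 * bestc > cov[j]) out += *bests;
    }
    if (cov[j] == 0) { out += draft[j]; continue; }
    int bb = -1, bc = -1;
    for (int t = 0; t < 4; ++t)
      if (bv[j][t] > bc) { bc = bv[j][t]; bb = t; }
    // prefer the draft base on ties
    int db = base2bit(draft[j]);
    if (db >= 0 && bv[j][db] == bc) bb = db;
    if (delv[j] > bc) continue;  // majority says this draft base is spurious
    out += BASES[bb];
  }
  return List::create(_["sequence"] = out, _["reads_used"] = used);
}
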