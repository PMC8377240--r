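#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <climits>
#include <random>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Seed-and-verify read mapper with a strict unique-mapping (co-optimality)
// filter, a wgsim-style paired-end simulator, and a pileup accumulator.
// The exported R-facing wrappers and the fused per-cell driver
// (cpp_run_cell) share the same core routines, so the streaming grid path
// is bit-identical to the modular simulate/map/pileup path.

static inline uint8_t bcode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};
static inline char compl_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// ---------------------------------------------------------------- k-mer index

typedef unsigned __int128 kmer_t;

struct KmerHash {
  size_t operator()(const kmer_t &x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    uint64_t h = lo * 0x9e3779b97f4a7c15ULL ^ (hi + 0x7f4a7c15ULL);
    h ^= h >> 33;
    return (size_t)h;
  }
};

struct MapIndex {
  int k;
  std::vector<std::vector<uint8_t>> codes;
  std::unordered_map<kmer_t, std::vector<uint64_t>, KmerHash> pos;  // chrom<<32|pos
};

static inline bool kmer_at(const std::vector<uint8_t> &code, size_t p, int k,
                           kmer_t &out) {
  kmer_t x = 0;
  for (int i = 0; i < k; i++) {
    uint8_t b = code[p + i];
    if (b > 3) return false;
    x = (x << 2) | (kmer_t)b;
  }
  out = x;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  MapIndex *idx = new MapIndex();
  idx->k = k;
  const int nc = seqs.size();
  idx->codes.resize(nc);
  for (int c = 0; c < nc; c++) {
    const char *s = CHAR(STRING_ELT(seqs, c));
    const size_t L = LENGTH(STRING_ELT(seqs, c));
    idx->codes[c].resize(L);
    for (size_t i = 0; i < L; i++) idx->codes[c][i] = bcode(s[i]);
    if (L < (size_t)k) continue;
    kmer_t x = 0;
    int valid = 0;
    const kmer_t mask = (((kmer_t)1) << (2 * k)) - 1;
    for (size_t i = 0; i < L; i++) {
      uint8_t b = idx->codes[c][i];
      if (b > 3) { valid = 0; x = 0; continue; }
      x = ((x << 2) | (kmer_t)b) & mask;
      valid++;
      if (valid >= k) {
        size_t p = i - k + 1;
        idx->pos[x].push_back(((uint64_t)c << 32) | (uint64_t)p);
      }
    }
  }
  XPtr<MapIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) {
  XPtr<MapIndex> idx(xp);
  return idx->k;
}

// [[Rcpp::export]]
IntegerMatrix cpp_index_lookup(SEXP xp, std::string kmer) {
  XPtr<MapIndex> idx(xp);
  std::vector<uint8_t> code(kmer.size());
  for (size_t i = 0; i < kmer.size(); i++) code[i] = bcode(kmer[i]);
  kmer_t x;
  if ((int)kmer.size() != idx->k || !kmer_at(code, 0, idx->k, x))
    return IntegerMatrix(0, 2);
  auto it = idx->pos.find(x);
  if (it == idx->pos.end()) return IntegerMatrix(0, 2);
  IntegerMatrix out(it->second.size(), 2);
  for (size_t i = 0; i < it->second.size(); i++) {
    out(i, 0) = (int)(it->second[i] >> 32);
    out(i, 1) = (int)(it->second[i] & 0xffffffffULL);
  }
  return out;
}

// ------------------------------------------------------------------- mapping

struct Cand { int32_t c; int32_t p; int mm; };

struct PairHit {
  bool mapped, unique;
  int32_t chrom, pos1, pos2;
  uint8_t strand1, strand2;  // 0 '+', 1 '-'
  int mm, nbest;
};

static int count_mm(const MapIndex &idx, const std::vector<uint8_t> &read,
                    int32_t c, int32_t p, int cap) {
  const std::vector<uint8_t> &g = idx.codes[c];
  const int len = (int)read.size();
  if (p < 0 || (size_t)p + (size_t)len > g.size()) return cap + 1;
  int mm = 0;
  for (int i = 0; i < len; i++) {
    if (g[p + i] != read[i]) {
      if (++mm > cap) return cap + 1;
    }
  }
  return mm;
}

static void gather_cands(const MapIndex &idx, const std::vector<uint8_t> &read,
                         int max_mm, std::vector<Cand> &out,
                         std::vector<int64_t> &starts) {
  out.clear();
  starts.clear();
  const int len = (int)read.size();
  const int k = idx.k;
  if (len < k) return;
  int offs[3] = {0, (len - k) / 2, len - k};
  for (int a = 0; a < 3; a++) {
    int off = offs[a];
    if (a > 0 && off == offs[a - 1]) continue;
    kmer_t x;
    if (!kmer_at(read, off, k, x)) continue;
    auto it = idx.pos.find(x);
    if (it == idx.pos.end()) continue;
    for (uint64_t enc : it->second) {
      int64_t c = (int64_t)(enc >> 32);
      int64_t p = (int64_t)(enc & 0xffffffffULL) - off;
      starts.push_back((c << 33) | ((p + 1) & 0x1ffffffffLL));
    }
  }
  std::sort(starts.begin(), starts.end());
  starts.erase(std::unique(starts.begin(), starts.end()), starts.end());
  for (int64_t s : starts) {
    int32_t c = (int32_t)(s >> 33);
    int32_t p = (int32_t)((s & 0x1ffffffffLL) - 1);
    int mm = count_mm(idx, read, c, p, max_mm);
    if (mm <= max_mm) {
      Cand cd; cd.c = c; cd.p = p; cd.mm = mm;
      out.push_back(cd);
    }
  }
}

struct MapScratch {
  std::vector<Cand> f1, r1, f2, r2;
  std::vector<int64_t> buf;
};

// map one pair given code arrays of both mates (as sequenced)
static PairHit map_pair_core(const MapIndex &idx,
                             const std::vector<uint8_t> &c1,
                             const std::vector<uint8_t> &c2,
                             int max_mm, double fmin, double fmax,
                             MapScratch &sc) {
  const int len1 = (int)c1.size(), len2 = (int)c2.size();
  std::vector<uint8_t> c1rc(c1.size()), c2rc(c2.size());
  for (int i = 0; i < len1; i++) {
    uint8_t b = c1[len1 - 1 - i];
    c1rc[i] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  for (int i = 0; i < len2; i++) {
    uint8_t b = c2[len2 - 1 - i];
    c2rc[i] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
  }
  gather_cands(idx, c1, max_mm, sc.f1, sc.buf);
  gather_cands(idx, c1rc, max_mm, sc.r1, sc.buf);
  gather_cands(idx, c2, max_mm, sc.f2, sc.buf);
  gather_cands(idx, c2rc, max_mm, sc.r2, sc.buf);

  PairHit h;
  h.mapped = h.unique = false;
  h.chrom = h.pos1 = h.pos2 = -1;
  h.strand1 = h.strand2 = 0;
  h.mm = -1; h.nbest = 0;

  int best = INT_MAX, cnt = 0;
  // config A: mate1 forward (left), mate2 reverse (right)
  for (const Cand &a : sc.f1) {
    for (const Cand &b : sc.r2) {
      if (a.c != b.c) continue;
      double frag = (double)(b.p + len2) - (double)a.p;
      if (frag < fmin || frag > fmax) continue;
      if (frag < (double)std::max(len1, len2)) continue;
      int s = a.mm + b.mm;
      if (s < best) {
        best = s; cnt = 1;
        h.chrom = a.c; h.pos1 = a.p; h.strand1 = 0; h.pos2 = b.p; h.strand2 = 1;
      } else if (s == best) cnt++;
    }
  }
  // config B: mate2 forward (left), mate1 reverse (right)
  for (const Cand &a : sc.f2) {
    for (const Cand &b : sc.r1) {
      if (a.c != b.c) continue;
      double frag = (double)(b.p + len1) - (double)a.p;
      if (frag < fmin || frag > fmax) continue;
      if (frag < (double)std::max(len1, len2)) continue;
      int s = a.mm + b.mm;
      if (s < best) {
        best = s; cnt = 1;
        h.chrom = a.c; h.pos1 = b.p; h.strand1 = 1; h.pos2 = a.p; h.strand2 = 0;
      } else if (s == best) cnt++;
    }
  }
  if (cnt > 0) {
    h.mapped = true;
    h.unique = (cnt == 1);
    h.mm = best;
    h.nbest = cnt;
  }
  return h;
}

// [[Rcpp::export]]
List cpp_map_pairs(SEXP xp, CharacterVector r1, CharacterVector r2,
                   int max_mm, double insert_mean, double insert_sd) {
  XPtr<MapIndex> idx(xp);
  const R_xlen_t n = r1.size();
  const double fmin = insert_mean - 4.0 * insert_sd;
  const double fmax = insert_mean + 4.0 * insert_sd;

  LogicalVector mapped(n), unique_(n);
  IntegerVector chrom(n), pos1(n), pos2(n), mm(n), nbest(n);
  CharacterVector strand1(n), strand2(n);

  MapScratch sc;
  std::vector<uint8_t> c1, c2;
  for (R_xlen_t t = 0; t < n; t++) {
    const char *s1 = CHAR(STRING_ELT(r1, t));
    const char *s2 = CHAR(STRING_ELT(r2, t));
    const int len1 = LENGTH(STRING_ELT(r1, t));
    const int len2 = LENGTH(STRING_ELT(r2, t));
    c1.assign(len1, 0); c2.assign(len2, 0);
    for (int i = 0; i < len1; i++) c1[i] = bcode(s1[i]);
    for (int i = 0; i < len2; i++) c2[i] = bcode(s2[i]);
    PairHit h = map_pair_core(*idx, c1, c2, max_mm, fmin, fmax, sc);
    mapped[t] = h.mapped; unique_[t] = h.unique;
    if (h.mapped) {
      chrom[t] = h.chrom; pos1[t] = h.pos1; pos2[t] = h.pos2;
      mm[t] = h.mm; nbest[t] = h.nbest;
      strand1[t] = h.strand1 == 0 ? "+" : "-";
      strand2[t] = h.strand2 == 0 ? "+" : "-";
    } else {
      chrom[t] = NA_INTEGER; pos1[t] = NA_INTEGER; pos2[t] = NA_INTEGER;
      mm[t] = NA_INTEGER; nbest[t] = 0;
      strand1[t] = NA_STRING; strand2[t] = NA_STRING;
    }
  }
  return List::create(_["mapped"] = mapped, _["unique"] = unique_,
                      _["chrom"] = chrom, _["pos1"] = pos1,
                      _["strand1"] = strand1, _["pos2"] = pos2,
                      _["strand2"] = strand2, _["mismatches"] = mm,
                      _["n_best"] = nbest);
}

// -------------------------------------------------------------------- pileup

struct Pileup {
  std::vector<std::vector<uint8_t>> ref;
  std::vector<std::vector<uint32_t>> cnt;  // 4 * L per chrom
};

// [[Rcpp::export]]
SEXP cpp_pileup_new(CharacterVector seqs) {
  Pileup *p = new Pileup();
  const int nc = seqs.size();
  p->ref.resize(nc);
  p->cnt.resize(nc);
  for (int c = 0; c < nc; c++) {
    const char *s = CHAR(STRING_ELT(seqs, c));
    const size_t L = LENGTH(STRING_ELT(seqs, c));
    p->ref[c].resize(L);
    for (size_t i = 0; i < L; i++) p->ref[c][i] = bcode(s[i]);
    p->cnt[c].assign(4 * L, 0u);
  }
  XPtr<Pileup> ptr(p, true);
  return ptr;
}

// add one aligned read; rev: read aligned as its reverse complement
static void pileup_add_read(Pileup &pu, int c, int32_t p0, bool rev,
                            const char *s, int len) {
  std::vector<uint32_t> &cnt = pu.cnt[c];
  const size_t L = pu.ref[c].size();
  for (int i = 0; i < len; i++) {
    int64_t gp = (int64_t)p0 + i;
    if (gp < 0 || (size_t)gp >= L) continue;
    char base = rev ? compl_base(s[len - 1 - i]) : s[i];
    uint8_t b = bcode(base);
    if (b < 4) cnt[4 * (size_t)gp + b]++;
  }
}

// [[Rcpp::export]]
void cpp_pileup_add(SEXP xp, IntegerVector chrom, IntegerVector pos,
                    CharacterVector strand, CharacterVector reads) {
  XPtr<Pileup> pu(xp);
  const R_xlen_t n = reads.size();
  for (R_xlen_t t = 0; t < n; t++) {
    if (chrom[t] == NA_INTEGER || pos[t] == NA_INTEGER) continue;
    const bool rev = (CHAR(STRING_ELT(strand, t))[0] == '-');
    pileup_add_read(*pu, chrom[t], pos[t], rev,
                    CHAR(STRING_ELT(reads, t)), LENGTH(STRING_ELT(reads, t)));
  }
}

// [[Rcpp::export]]
DataFrame cpp_pileup_sites(SEXP xp, int min_depth) {
  XPtr<Pileup> pu(xp);
  std::vector<int> oc, op, da, dc, dg, dt;
  std::vector<std::string> oref;
  for (size_t c = 0; c < pu->ref.size(); c++) {
    const size_t L = pu->ref[c].size();
    for (size_t i = 0; i < L; i++) {
      uint32_t *q = &pu->cnt[c][4 * i];
      uint32_t depth = q[0] + q[1] + q[2] + q[3];
      if ((int)depth >= min_depth) {
        oc.push_back((int)c); op.push_back((int)i);
        oref.push_back(std::string(1, "ACGTN"[pu->ref[c][i]]));
        da.push_back(q[0]); dc.push_back(q[1]); dg.push_back(q[2]);
        dt.push_back(q[3]);
      }
    }
  }
  return DataFrame::create(_["chrom"] = oc, _["pos"] = op, _["ref"] = oref,
                           _["A"] = da, _["C"] = dc, _["G"] = dg, _["T"] = dt,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_pileup_call(SEXP xp, int min_depth, int min_alt_count,
                          double min_alt_frac, double hom_frac) {
  XPtr<Pileup> pu(xp);
  std::vector<int> oc, op, odepth, oaltc, ohom;
  std::vector<std::string> oref, oalt;
  std::vector<double> ofrac;
  for (size_t c = 0; c < pu->ref.size(); c++) {
    const size_t L = pu->ref[c].size();
    for (size_t i = 0; i < L; i++) {
      uint8_t rb = pu->ref[c][i];
      if (rb > 3) continue;
      const uint32_t *q = &pu->cnt[c][4 * i];
      uint32_t depth = q[0] + q[1] + q[2] + q[3];
      if ((int)depth < min_depth) continue;
      int alt = -1; uint32_t altc = 0;
      for (int b = 0; b < 4; b++) {  // lexicographic tie-break: first wins
        if (b == rb) continue;
        if (q[b] > altc) { altc = q[b]; alt = b; }
      }
      if (alt < 0 || (int)altc < min_alt_count) continue;
      double frac = (double)altc / (double)depth;
      if (frac < min_alt_frac) continue;
      oc.push_back((int)c); op.push_back((int)i);
      oref.push_back(std::string(1, BASES[rb]));
      oalt.push_back(std::string(1, BASES[alt]));
      odepth.push_back((int)depth); oaltc.push_back((int)altc);
      ofrac.push_back(frac);
      ohom.push_back(frac >= hom_frac ? 1 : 0);
    }
  }
  return DataFrame::create(_["chrom"] = oc, _["pos"] = op, _["ref"] = oref,
                           _["alt"] = oalt, _["depth"] = odepth,
                           _["alt_count"] = oaltc, _["alt_frac"] = ofrac,
                           _["hom"] = ohom, _["stringsAsFactors"] = false);
}

// ----------------------------------------------------------------- simulator

struct SimCore {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;
  std::normal_distribution<double> norm;
  std::vector<const char *> h1, h2;
  std::vector<size_t> len;
  std::vector<double> cum;
  double tot;
  int read_len, min_frag;
  double error_rate;

  SimCore(CharacterVector hap1, CharacterVector hap2, int read_len_,
          double insert_mean, double insert_sd, double error_rate_,
          uint64_t seed)
      : rng(seed), unif(0.0, 1.0), norm(insert_mean, insert_sd),
        read_len(read_len_), min_frag(2 * read_len_),
        error_rate(error_rate_) {
    const int nc = hap1.size();
    h1.resize(nc); h2.resize(nc); len.resize(nc); cum.resize(nc);
    tot = 0;
    for (int c = 0; c < nc; c++) {
      h1[c] = CHAR(STRING_ELT(hap1, c));
      h2[c] = CHAR(STRING_ELT(hap2, c));
      len[c] = LENGTH(STRING_ELT(hap1, c));
      tot += (double)len[c];
      cum[c] = tot;
    }
  }

  // one fragment -> left/right read buffers (as sequenced)
  void draw(std::string &left, std::string &right, int &chrom, size_t &start,
            int &frag, int &hap, bool &flip) {
    double u = unif(rng) * tot;
    int c = 0;
    while (c < (int)cum.size() - 1 && u > cum[c]) c++;
    do {
      frag = (int)std::lround(norm(rng));
    } while (frag < min_frag || (size_t)frag > len[c]);
    start = (size_t)(unif(rng) * (double)(len[c] - frag + 1));
    if (start > len[c] - frag) start = len[c] - frag;
    hap = unif(rng) < 0.5 ? 1 : 2;
    const char *hs = hap == 1 ? h1[c] : h2[c];
    left.resize(read_len); right.resize(read_len);
    for (int i = 0; i < read_len; i++) left[i] = hs[start + i];
    for (int i = 0; i < read_len; i++)
      right[i] = compl_base(hs[start + frag - 1 - i]);
    if (error_rate > 0) {
      std::string *mates[2] = {&left, &right};
      const double q = std::log(1.0 - error_rate);
      for (int m = 0; m < 2; m++) {
        std::string &rd = *mates[m];
        int i = -1;
        while (true) {
          double g = std::log(1.0 - unif(rng)) / q;
          i += 1 + (int)g;
          if (i >= read_len) break;
          uint8_t oc = bcode(rd[i]);
          if (oc > 3) continue;
          uint8_t nb = (uint8_t)((oc + 1 + (int)(unif(rng) * 3.0)) & 3);
          if (nb == oc) nb = (nb + 1) & 3;
          rd[i] = BASES[nb];
        }
      }
    }
    flip = unif(rng) < 0.5;
    chrom = c;
  }
};

// [[Rcpp::export]]
List cpp_simulate_pairs(CharacterVector hap1, CharacterVector hap2,
                        int n_pairs, int read_len, double insert_mean,
                        double insert_sd, double error_rate, double seed) {
  SimCore sim(hap1, hap2, read_len, insert_mean, insert_sd, error_rate,
              (uint64_t)seed);
  CharacterVector r1(n_pairs), r2(n_pairs);
  IntegerVector t_chrom(n_pairs), t_start(n_pairs), t_flen(n_pairs),
      t_hap(n_pairs);
  LogicalVector t_flip(n_pairs);
  std::string left, right;
  for (int t = 0; t < n_pairs; t++) {
    int chrom, frag, hap; size_t start; bool flip;
    sim.draw(left, right, chrom, start, frag, hap, flip);
    if (!flip) { r1[t] = left; r2[t] = right; }
    else       { r1[t] = right; r2[t] = left; }
    t_chrom[t] = chrom; t_start[t] = (int)start; t_flen[t] = frag;
    t_hap[t] = hap; t_flip[t] = flip;
  }
  return List::create(_["read1"] = r1, _["read2"] = r2, _["chrom"] = t_chrom,
                      _["frag_start"] = t_start, _["frag_len"] = t_flen,
                      _["haplotype"] = t_hap, _["flip"] = t_flip);
}

// Fused per-cell driver: simulate, map and accumulate the pileup without
// materialising reads in R. Uses the same SimCore / map_pair_core /
// pileup_add_read as the modular path.
// [[Rcpp::export]]
IntegerVector cpp_run_cell(SEXP index_xp, SEXP pileup_xp,
                           CharacterVector hap1, CharacterVector hap2,
                           int n_pairs, int read_len, double insert_mean,
                           double insert_sd, double error_rate, int max_mm,
                           double seed) {
  XPtr<MapIndex> idx(index_xp);
  XPtr<Pileup> pu(pileup_xp);
  SimCore sim(hap1, hap2, read_len, insert_mean, insert_sd, error_rate,
              (uint64_t)seed);
  const double fmin = insert_mean - 4.0 * insert_sd;
  const double fmax = insert_mean + 4.0 * insert_sd;
  MapScratch sc;
  std::string left, right;
  std::vector<uint8_t> c1(read_len), c2(read_len);
  int n_mapped = 0, n_unique = 0;
  for (int t = 0; t < n_pairs; t++) {
    int chrom, frag, hap; size_t start; bool flip;
    sim.draw(left, right, chrom, start, frag, hap, flip);
    const std::string &m1 = flip ? right : left;
    const std::string &m2 = flip ? left : right;
    for (int i = 0; i < read_len; i++) c1[i] = bcode(m1[i]);
    for (int i = 0; i < read_len; i++) c2[i] = bcode(m2[i]);
    PairHit h = map_pair_core(*idx, c1, c2, max_mm, fmin, fmax, sc);
    if (h.mapped) n_mapped++;
    if (h.unique) {
      n_unique++;
      pileup_add_read(*pu, h.chrom, h.pos1, h.strand1 == 1, m1.c_str(),
                      read_len);
      pileup_add_read(*pu, h.chrom, h.pos2, h.strand2 == 1, m2.c_str(),
                      read_len);
    }
  }
  return IntegerVector::create(_["pairs_total"] = n_pairs,
                               _["pairs_mapped"] = n_mapped,
                               _["pairs_unique"] = n_unique);
}
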