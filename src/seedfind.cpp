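#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// Exact multi-hit seed-window enumeration and lockstep run merging.
// Windows of length w are hashed (polynomial rolling hash over both strands),
// grouped by canonical hash, and verified by direct base comparison, so hash
// collisions cannot produce false occurrences.

static inline uint8_t base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N or anything else
  }
}

static std::vector<uint8_t> encode_seq(const char *s, size_t L) {
  std::vector<uint8_t> code(L);
  for (size_t i = 0; i < L; i++) code[i] = base_code(s[i]);
  return code;
}

// hashes of all w-windows: h(p) = sum (code[p+i]+1) * B^(w-1-i)  (mod 2^64)
static std::vector<uint64_t> window_hashes(const std::vector<uint8_t> &code,
                                           int w, uint64_t B) {
  const size_t L = code.size();
  std::vector<uint64_t> h;
  if (L < (size_t)w) return h;
  const size_t n = L - w + 1;
  h.resize(n);
  uint64_t Bw = 1;
  for (int i = 0; i < w - 1; i++) Bw *= B;
  uint64_t cur = 0;
  for (int i = 0; i < w; i++) cur = cur * B + (uint64_t)(code[i] + 1);
  h[0] = cur;
  for (size_t p = 1; p < n; p++) {
    cur = (cur - (uint64_t)(code[p - 1] + 1) * Bw) * B + (uint64_t)(code[p + w - 1] + 1);
    h[p] = cur;
  }
  return h;
}

struct SeedRow {
  int32_t sc; int32_t sp;   // seed window (chrom index, 0-based pos)
  int32_t oc; int32_t op;   // occurrence (chrom index, 0-based pos)
  uint8_t ostrand;          // 0 = '+', 1 = '-'
};

// window equality checks on code arrays (windows are known N-free)
static inline bool win_eq_fwd(const std::vector<uint8_t> &a, int32_t pa,
                              const std::vector<uint8_t> &b, int32_t pb, int w) {
  for (int i = 0; i < w; i++)
    if (a[pa + i] != b[pb + i]) return false;
  return true;
}

static inline bool win_eq_rc(const std::vector<uint8_t> &a, int32_t pa,
                             const std::vector<uint8_t> &b, int32_t pb, int w) {
  // true when window b equals reverse complement of window a
  for (int i = 0; i < w; i++)
    if (b[pb + i] != (uint8_t)(3 - a[pa + w - 1 - i])) return false;
  return true;
}

// [[Rcpp::export]]
List cpp_seed_hits(CharacterVector seqs, int w, bool both_strands, int step) {
  const uint64_t B = 1099511628211ULL;  // odd => injective multiplication mod 2^64
  const int nchrom = seqs.size();

  std::vector<std::vector<uint8_t>> codes(nchrom);
  for (int c = 0; c < nchrom; c++) {
    const char *s = CHAR(STRING_ELT(seqs, c));
    codes[c] = encode_seq(s, LENGTH(STRING_ELT(seqs, c)));
  }

  // (canonical hash, encoded window id) for every N-free window
  std::vector<std::pair<uint64_t, uint64_t>> keyed;
  for (int c = 0; c < nchrom; c++) {
    const std::vector<uint8_t> &code = codes[c];
    const size_t L = code.size();
    if (L < (size_t)w) continue;
    std::vector<uint64_t> hf = window_hashes(code, w, B);
    std::vector<uint64_t> hr;
    if (both_strands) {
      std::vector<uint8_t> rc(L);
      for (size_t i = 0; i < L; i++) {
        uint8_t b = code[L - 1 - i];
        rc[i] = b < 4 ? (uint8_t)(3 - b) : (uint8_t)4;
      }
      hr = window_hashes(rc, w, B);
    }
    // sliding N count
    int ncount = 0;
    for (int i = 0; i < w; i++) ncount += (code[i] == 4);
    const size_t n = L - w + 1;
    for (size_t p = 0; p < n; p++) {
      if (p > 0) {
        ncount -= (code[p - 1] == 4);
        ncount += (code[p + w - 1] == 4);
      }
      if (ncount == 0) {
        uint64_t key = hf[p];
        if (both_strands) {
          uint64_t kr = hr[L - w - p];
          if (kr < key) key = kr;
        }
        keyed.emplace_back(key, ((uint64_t)c << 32) | (uint64_t)p);
      }
    }
  }

  std::sort(keyed.begin(), keyed.end());

  std::vector<SeedRow> rows;
  std::vector<int32_t> mc, mp;        // bucket members
  std::vector<int32_t> cls;           // class id per member
  std::vector<uint8_t> orient;        // orientation vs class representative

  size_t i = 0;
  const size_t nk = keyed.size();
  while (i < nk) {
    size_t j = i + 1;
    while (j < nk && keyed[j].first == keyed[i].first) j++;
    const size_t m = j - i;
    if (m >= 2) {
      mc.clear(); mp.clear(); cls.clear(); orient.clear();
      for (size_t t = i; t < j; t++) {
        mc.push_back((int32_t)(keyed[t].second >> 32));
        mp.push_back((int32_t)(keyed[t].second & 0xffffffffULL));
      }
      // partition into verified identity classes (hash collisions split here)
      std::vector<size_t> reps;  // representative member index per class
      for (size_t t = 0; t < m; t++) {
        int assigned = -1; uint8_t ori = 0;
        for (size_t r = 0; r < reps.size(); r++) {
          size_t rr = reps[r];
          if (win_eq_fwd(codes[mc[rr]], mp[rr], codes[mc[t]], mp[t], w)) {
            assigned = (int)r; ori = orient[rr]; break;
          }
          if (both_strands &&
              win_eq_rc(codes[mc[rr]], mp[rr], codes[mc[t]], mp[t], w)) {
            assigned = (int)r; ori = (uint8_t)(1 - orient[rr]); break;
          }
        }
        if (assigned < 0) {
          reps.push_back(t);
          cls.push_back((int32_t)reps.size() - 1);
          orient.push_back(0);  // representative is '+' by convention; fixed below
          // representative orientation must be relative to the FIRST rep of
          // its own class, which is itself => 0 is correct
        } else {
          cls.push_back(assigned);
          orient.push_back(ori);
        }
      }
      // emit rows per class with >= 2 members
      std::vector<int> clsize(reps.size(), 0);
      for (size_t t = 0; t < m; t++) clsize[cls[t]]++;
      for (size_t a = 0; a < m; a++) {
        if (clsize[cls[a]] < 2) continue;
        if (step > 1 && (mp[a] % step) != 0) continue;
        for (size_t b = 0; b < m; b++) {
          if (cls[b] != cls[a]) continue;
          SeedRow r;
          r.sc = mc[a]; r.sp = mp[a];
          r.oc = mc[b]; r.op = mp[b];
          r.ostrand = (uint8_t)(orient[a] == orient[b] ? 0 : 1);
          rows.push_back(r);
        }
      }
    }
    i = j;
  }

  std::sort(rows.begin(), rows.end(), [](const SeedRow &x, const SeedRow &y) {
    if (x.sc != y.sc) return x.sc < y.sc;
    if (x.sp != y.sp) return x.sp < y.sp;
    if (x.oc != y.oc) return x.oc < y.oc;
    if (x.ostrand != y.ostrand) return x.ostrand < y.ostrand;
    return x.op < y.op;
  });

  const size_t nr = rows.size();
  IntegerVector sc(nr), sp(nr), oc(nr), op(nr), ostr(nr);
  for (size_t t = 0; t < nr; t++) {
    sc[t] = rows[t].sc; sp[t] = rows[t].sp;
    oc[t] = rows[t].oc; op[t] = rows[t].op;
    ostr[t] = rows[t].ostrand;
  }
  return List::create(_["seed_chrom"] = sc, _["seed_pos"] = sp,
                      _["occ_chrom"] = oc, _["occ_pos"] = op,
                      _["occ_strand"] = ostr);
}

struct Occ { int32_t c; int32_t p; uint8_t s; };

// Merge maximal runs of consecutive seed windows whose occurrence sets shift
// in lockstep (+1 for '+' occurrences, -1 for '-' occurrences). Occurrence
// sets must be sorted by (chrom, strand, pos), as cpp_seed_hits emits them.
// [[Rcpp::export]]
List cpp_merge_runs(IntegerVector seed_chrom, IntegerVector seed_pos,
                    IntegerVector occ_chrom, IntegerVector occ_pos,
                    IntegerVector occ_strand, int w) {
  const R_xlen_t n = seed_chrom.size();

  // window boundaries
  std::vector<R_xlen_t> wstart;
  for (R_xlen_t t = 0; t < n; t++) {
    if (t == 0 || seed_chrom[t] != seed_chrom[t - 1] || seed_pos[t] != seed_pos[t - 1])
      wstart.push_back(t);
  }
  wstart.push_back(n);
  const size_t nwin = wstart.size() > 0 ? wstart.size() - 1 : 0;

  std::unordered_set<std::string> seen;
  std::vector<int> g_len, g_nloci;
  std::vector<int> l_gid, l_chrom, l_start;
  std::vector<int> l_strand;  // 0 '+', 1 '-'
  int next_gid = 0;

  auto lockstep = [&](size_t a, size_t b) -> bool {
    // window b must follow window a at pos+1 on same chrom with shifted set
    R_xlen_t a0 = wstart[a], a1 = wstart[a + 1];
    R_xlen_t b0 = wstart[b], b1 = wstart[b + 1];
    if (a1 - a0 != b1 - b0) return false;
    if (seed_chrom[b0] != seed_chrom[a0] || seed_pos[b0] != seed_pos[a0] + 1)
      return false;
    for (R_xlen_t k = 0; k < a1 - a0; k++) {
      if (occ_chrom[b0 + k] != occ_chrom[a0 + k]) return false;
      if (occ_strand[b0 + k] != occ_strand[a0 + k]) return false;
      int shift = occ_strand[a0 + k] == 0 ? 1 : -1;
      if (occ_pos[b0 + k] != occ_pos[a0 + k] + shift) return false;
    }
    return true;
  };

  auto emit = [&](size_t first, size_t last) {
    R_xlen_t f0 = wstart[first], f1 = wstart[first + 1];
    int r = seed_pos[wstart[last]] - seed_pos[f0] + 1;  // run length in windows
    int len = r + w - 1;
    std::vector<Occ> loci;
    for (R_xlen_t k = f0; k < f1; k++) {
      Occ o;
      o.c = occ_chrom[k];
      o.s = (uint8_t)occ_strand[k];
      o.p = o.s == 0 ? occ_pos[k] : occ_pos[k] - r + 1;
      loci.push_back(o);
    }
    std::sort(loci.begin(), loci.end(), [](const Occ &x, const Occ &y) {
      if (x.c != y.c) return x.c < y.c;
      if (x.p != y.p) return x.p < y.p;
      return x.s < y.s;
    });
    bool flip = loci[0].s == 1;  // canonical: first locus on '+'
    std::string sig = std::to_string(len);
    for (auto &o : loci) {
      uint8_t s = flip ? (uint8_t)(1 - o.s) : o.s;
      sig += "|" + std::to_string(o.c) + "," + std::to_string(o.p) + "," +
             std::to_string((int)s);
    }
    if (seen.insert(sig).second) {
      int gid = next_gid++;
      g_len.push_back(len);
      g_nloci.push_back((int)loci.size());
      for (auto &o : loci) {
        l_gid.push_back(gid);
        l_chrom.push_back(o.c);
        l_start.push_back(o.p);
        l_strand.push_back(flip ? 1 - (int)o.s : (int)o.s);
      }
    }
  };

  size_t run_first = 0;
  for (size_t t = 0; t + 1 <= nwin; t++) {
    bool cont = (t + 1 < nwin) && lockstep(t, t + 1);
    if (!cont) {
      if (nwin > 0) emit(run_first, t);
      run_first = t + 1;
    }
  }

  return List::create(
      _["group_length"] = IntegerVector(g_len.begin(), g_len.end()),
      _["group_nloci"] = IntegerVector(g_nloci.begin(), g_nloci.end()),
      _["locus_gid"] = IntegerVector(l_gid.begin(), l_gid.end()),
      _["locus_chrom"] = IntegerVector(l_chrom.begin(), l_chrom.end()),
      _["locus_start"] = IntegerVector(l_start.begin(), l_start.end()),
      _["locus_strand"] = IntegerVector(l_strand.begin(), l_strand.end()));
}
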