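#include <Rcpp.h>
#include <bitset>
#include <cstring>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// sequence utilities
// ---------------------------------------------------------------------------

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  case 'N': return 'N'; case 'n': return 'n';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    out[i] = revcomp_str(std::string(x[i]));
  }
  return out;
}

// 32-bit FNV-1a hash, returned as 8-char hex (stable sequence-derived ids)
// [[Rcpp::export]]
CharacterVector cpp_seq_hash(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[9];
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s(x[i]);
    uint32_t h = 2166136261u;
    for (size_t k = 0; k < s.size(); ++k) {
      h ^= (uint32_t)(unsigned char)s[k];
      h *= 16777619u;
    }
    snprintf(buf, sizeof(buf), "%08x", h);
    out[i] = buf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// pairwise identity
//
// Global alignment maximising the number of matching columns (match +1,
// mismatch 0, gap 0); among alignments with maximal matches the one with the
// fewest columns is taken. identity = matches / columns.
// ---------------------------------------------------------------------------

static void identity_dp(const std::string& a, const std::string& b,
                        int& matches, int& columns) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> Mprev(m + 1), Cprev(m + 1), Mcur(m + 1), Ccur(m + 1);
  for (int j = 0; j <= m; ++j) { Mprev[j] = 0; Cprev[j] = j; }
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = 0; Ccur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int bm = Mprev[j - 1] + (a[i - 1] == b[j - 1] ? 1 : 0);
      int bc = Cprev[j - 1] + 1;
      if (Mprev[j] > bm || (Mprev[j] == bm && Cprev[j] + 1 < bc)) {
        bm = Mprev[j]; bc = Cprev[j] + 1;
      }
      if (Mcur[j - 1] > bm || (Mcur[j - 1] == bm && Ccur[j - 1] + 1 < bc)) {
        bm = Mcur[j - 1]; bc = Ccur[j - 1] + 1;
      }
      Mcur[j] = bm; Ccur[j] = bc;
    }
    std::swap(Mprev, Mcur); std::swap(Cprev, Ccur);
  }
  matches = Mprev[m];
  columns = Cprev[m];
}

// [[Rcpp::export]]
double cpp_pairwise_identity(std::string a, std::string b) {
  if (a.empty() || b.empty())
    stop("sequences must be non-empty");
  int M, C;
  identity_dp(a, b, M, C);
  return (double)M / (double)C;
}

// ---------------------------------------------------------------------------
// greedy abundance-ordered centroid clustering
//
// `seqs` must already be sorted (descending total count, ties lexicographic).
// Each sequence joins the first centroid, in founding order, with identity >=
// threshold, else founds a new cluster. Two exact-safe prescreens (a length
// ratio bound and a q-gram count lower bound) skip pairs that provably cannot
// reach the threshold; they never skip a qualifying pair, so the result is
// identical to the plain quadratic pass.
// ---------------------------------------------------------------------------

static const int QGRAM = 5;
static const int QSPACE = 1 << (2 * QGRAM); // 4^5

static inline int base_code(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// collect q-gram codes; returns false if sequence has non-ACGT letters
static bool qgram_codes(const std::string& s, std::vector<int>& codes) {
  codes.clear();
  const int L = (int)s.size();
  if (L < QGRAM) return true;
  int code = 0, valid = 0;
  const int mask = QSPACE - 1;
  for (int i = 0; i < L; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { return false; }
    code = ((code << 2) | b) & mask;
    if (++valid >= QGRAM) codes.push_back(code);
  }
  return true;
}

// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double threshold) {
  const R_xlen_t n = seqs.size();
  IntegerVector assign(n);
  std::vector<std::string> cents;              // centroid sequences
  std::vector<std::bitset<QSPACE>*> cbits;     // q-gram presence per centroid
  std::vector<bool> cfilt;                     // centroid filterable?
  std::vector<int> clen;
  std::vector<int> codes;
  const double eps = 1e-9;

  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s(seqs[i]);
    const int ls = (int)s.size();
    bool sfilt = qgram_codes(s, codes);
    int joined = 0;
    for (size_t c = 0; c < cents.size(); ++c) {
      const int lc = clen[c];
      const int mn = std::min(ls, lc), mx = std::max(ls, lc);
      // identity <= min/max
      if ((double)mn + eps < threshold * (double)mx) continue;
      if (sfilt && cfilt[c] && mn >= QGRAM) {
        // identity >= t implies edit distance <= floor(min*(1-t)/t), which
        // implies >= (max - q + 1) - k*q common q-grams
        int k = (int)std::floor((double)mn * (1.0 - threshold) / threshold + eps);
        int need = (mx - QGRAM + 1) - k * QGRAM;
        if (need > 0) {
          int shared = 0;
          const std::bitset<QSPACE>& bs = *cbits[c];
          int remaining = (int)codes.size();
          for (size_t q = 0; q < codes.size(); ++q, --remaining) {
            if (bs[codes[q]]) ++shared;
            if (shared + remaining < need) break;
          }
          if (shared < need) continue;
        }
      }
      int M, C;
      identity_dp(s, cents[c], M, C);
      if ((double)M + eps >= threshold * (double)C) { joined = (int)c + 1; break; }
    }
    if (joined == 0) {
      cents.push_back(s);
      clen.push_back(ls);
      std::bitset<QSPACE>* bs = new std::bitset<QSPACE>();
      if (sfilt) for (size_t q = 0; q < codes.size(); ++q) bs->set(codes[q]);
      cbits.push_back(bs);
      cfilt.push_back(sfilt);
      joined = (int)cents.size();
    }
    assign[i] = joined;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  for (size_t c = 0; c < cbits.size(); ++c) delete cbits[c];
  return assign;
}

// ---------------------------------------------------------------------------
// demultiplexing
// ---------------------------------------------------------------------------

static inline bool prefix_match(const std::string& read, const std::string& bc,
                                int max_mm) {
  if (read.size() < bc.size()) return false;
  int mm = 0;
  for (size_t i = 0; i < bc.size(); ++i) {
    if (read[i] != bc[i] && ++mm > max_mm) return false;
  }
  return true;
}

// sample: 1..K entry index, 0 = no match, -1 = ambiguous (>= 2 entries)
// swapped: read1/read2 matched in exchanged roles
// [[Rcpp::export]]
List cpp_demux(CharacterVector r1, CharacterVector r2,
               CharacterVector bc_fwd, CharacterVector bc_rev, int max_mm) {
  const R_xlen_t n = r1.size();
  const int K = (int)bc_fwd.size();
  std::vector<std::string> bf(K), br(K);
  for (int k = 0; k < K; ++k) { bf[k] = bc_fwd[k]; br[k] = bc_rev[k]; }
  IntegerVector sample(n);
  LogicalVector swapped(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a(r1[i]), b(r2[i]);
    int hit = 0, nhits = 0; bool sw = false;
    for (int k = 0; k < K; ++k) {
      bool fwd_ok = prefix_match(a, bf[k], max_mm) && prefix_match(b, br[k], max_mm);
      bool rev_ok = prefix_match(b, bf[k], max_mm) && prefix_match(a, br[k], max_mm);
      if (fwd_ok || rev_ok) {
        ++nhits; hit = k + 1; sw = !fwd_ok && rev_ok;
        if (nhits > 1) break;
      }
    }
    if (nhits == 0) sample[i] = 0;
    else if (nhits > 1) sample[i] = -1;
    else { sample[i] = hit; swapped[i] = sw; }
  }
  return List::create(_["sample"] = sample, _["swapped"] = swapped);
}

// ---------------------------------------------------------------------------
// pair merging + variable-region extraction
// ---------------------------------------------------------------------------

// leftmost (or rightmost) occurrence of pat in text with <= max_mm mismatches
static int find_approx(const std::string& text, const std::string& pat,
                       int max_mm, bool rightmost, int from = 0) {
  const int lt = (int)text.size(), lp = (int)pat.size();
  if (lp == 0 || lp > lt) return -1;
  int found = -1;
  for (int off = from; off <= lt - lp; ++off) {
    int mm = 0; bool ok = true;
    for (int j = 0; j < lp; ++j) {
      if (text[off + j] != pat[j] && ++mm > max_mm) { ok = false; break; }
    }
    if (ok) {
      if (!rightmost) return off;
      found = off;
    }
  }
  return found;
}

// maximal exact suffix(fwd)-prefix(rc) overlap >= min_overlap
static bool merge_overlap(const std::string& fwd, const std::string& rc,
                          int min_overlap, std::string& merged) {
  const int lf = (int)fwd.size(), lr = (int)rc.size();
  for (int o = std::min(lf, lr); o >= min_overlap; --o) {
    if (fwd.compare(lf - o, o, rc, 0, o) == 0) {
      merged = fwd.substr(0, lf - o) + rc;
      return true;
    }
  }
  return false;
}

// try to cut the variable region out of one assembled (or single-read)
// candidate string; returns reason code (0 ok / 2 constants not found /
// 3 length out of range / 4 ambiguous base)
static int try_extract(const std::string& cand, const std::string& fc,
                       const std::string& rc, int const_mm,
                       int vmin, int vmax, std::string& var) {
  int p1 = find_approx(cand, fc, const_mm, false);
  if (p1 < 0) return 2;
  int p2 = find_approx(cand, rc, const_mm, true, p1 + (int)fc.size());
  if (p2 < 0) return 2;
  int start = p1 + (int)fc.size();
  int len = p2 - start;
  if (len < vmin || len > vmax) return 3;
  var = cand.substr(start, len);
  for (size_t i = 0; i < var.size(); ++i) {
    char c = var[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return 4;
  }
  return 0;
}

// reason codes: 0 ok, 1 merge_failed, 2 constant_mismatch,
//               3 length_out_of_range, 4 ambiguous_base
// [[Rcpp::export]]
List cpp_extract_variable(CharacterVector fwd, CharacterVector rev,
                          std::string fwd_const, std::string rev_const,
                          int vmin, int vmax, int const_mm,
                          int min_overlap, bool allow_unmerged) {
  const R_xlen_t n = fwd.size();
  CharacterVector variable(n);
  IntegerVector reason(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string f(fwd[i]);
    std::string rc = revcomp_str(std::string(rev[i]));
    std::string merged, var;
    bool ok_merge = merge_overlap(f, rc, min_overlap, merged);
    int code;
    if (ok_merge) {
      code = try_extract(merged, fwd_const, rev_const, const_mm, vmin, vmax, var);
    } else if (allow_unmerged) {
      code = try_extract(f, fwd_const, rev_const, const_mm, vmin, vmax, var);
      if (code == 2) {
        int code2 = try_extract(rc, fwd_const, rev_const, const_mm, vmin, vmax, var);
        // constants found in neither single read: report as failed merge
        code = (code2 == 2) ? 1 : code2;
      }
    } else {
      code = 1;
    }
    if (code == 0) variable[i] = var; else variable[i] = NA_STRING;
    reason[i] = code;
    if ((i & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["variable"] = variable, _["reason"] = reason);
}

// ---------------------------------------------------------------------------
// i.i.d. substitution errors (uses R's RNG; reproducible under set.seed)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_add_errors(CharacterVector seqs, double rate) {
  RNGScope scope;
  const R_xlen_t n = seqs.size();
  static const char* alt[4] = { "CGT", "AGT", "ACT", "ACG" };
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s(seqs[i]);
    int L = (int)s.size();
    int k = (int)R::rbinom((double)L, rate);
    if (k > 0) {
      for (int e = 0; e < k; ++e) {
        int pos = (int)(R::unif_rand() * L);
        if (pos >= L) pos = L - 1;
        int b = base_code(s[pos]);
        if (b < 0) continue;
        int a = (int)(R::unif_rand() * 3.0);
        if (a > 2) a = 2;
        s[pos] = alt[b][a];
      }
    }
    out[i] = s;
  }
  return out;
}
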