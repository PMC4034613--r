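// Core sequence kernels: seeded ungapped alignment with best/second-best
// score semantics, paired-consensus classification scoring, pileup base
// counting, and quality end-trim bounds. Coordinates are 0-based half-open
// throughout; the R layer converts where an external format requires 1-based.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

struct SeqIndex {
  int k;
  std::vector<std::string> seqs;
  // kmer -> list of (target, position)
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > map;
  size_t n_positions;
};

static void index_sequence(SeqIndex& idx, const std::string& s, int32_t t) {
  const int k = idx.k;
  const int64_t L = (int64_t)s.size();
  if (L < k) return;
  uint64_t key = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;  // valid bases accumulated
  for (int64_t i = 0; i < L; ++i) {
    int c = base_code(s[i]);
    if (c > 3) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      idx.map[key].push_back(std::make_pair(t, (int32_t)(i - k + 1)));
      ++idx.n_positions;
    }
  }
}

// [[Rcpp::export(name = ".cpp_build_index")]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  if (k < 4 || k > 32) stop("seed length k must be between 4 and 32");
  SeqIndex* idx = new SeqIndex();
  idx->k = k;
  idx->n_positions = 0;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    std::string s = as<std::string>(seqs[t]);
    idx->seqs.push_back(s);
    index_sequence(*idx, s, (int32_t)t);
  }
  XPtr<SeqIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".cpp_index_positions")]]
double cpp_index_positions(SEXP xp) {
  XPtr<SeqIndex> idx(xp);
  return (double)idx->n_positions;
}

struct Cand {
  int32_t t;
  int32_t start;
  int strand;  // 0 = '+', 1 = '-'
  bool operator<(const Cand& o) const {
    if (t != o.t) return t < o.t;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
  bool operator==(const Cand& o) const {
    return t == o.t && start == o.start && strand == o.strand;
  }
};

static void gather_candidates(const SeqIndex& idx, const std::string& seq,
                              int strand, std::vector<Cand>& out) {
  const int k = idx.k;
  const int64_t L = (int64_t)seq.size();
  if (L < k) return;
  std::vector<int64_t> offsets;
  for (int64_t o = 0; o + k <= L; o += k) offsets.push_back(o);
  if (offsets.empty() || offsets.back() != L - k) offsets.push_back(L - k);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t j = 0; j < offsets.size(); ++j) {
    int64_t o = offsets[j];
    uint64_t key = 0;
    bool ok = true;
    for (int i = 0; i < k; ++i) {
      int c = base_code(seq[o + i]);
      if (c > 3) { ok = false; break; }
      key = ((key << 2) | (uint64_t)c) & mask;
    }
    if (!ok) continue;
    std::unordered_map<uint64_t,
      std::vector<std::pair<int32_t, int32_t> > >::const_iterator it =
        idx.map.find(key);
    if (it == idx.map.end()) continue;
    const std::vector<std::pair<int32_t, int32_t> >& hits = it->second;
    for (size_t h = 0; h < hits.size(); ++h) {
      int64_t start = (int64_t)hits[h].second - o;
      if (start < 0) continue;
      if (start + L > (int64_t)idx.seqs[hits[h].first].size()) continue;
      Cand c;
      c.t = hits[h].first;
      c.start = (int32_t)start;
      c.strand = strand;
      out.push_back(c);
    }
  }
}

static void score_ungapped(const std::string& target, int64_t start,
                           const std::string& read, int mismatch_pen,
                           int n_pen, int& score, int& mismatches) {
  int s = 0, mm = 0;
  for (size_t i = 0; i < read.size(); ++i) {
    int a = base_code(read[i]);
    int b = base_code(target[start + i]);
    if (a > 3 || b > 3) {
      s -= n_pen;
    } else if (a != b) {
      s -= mismatch_pen;
      ++mm;
    }
  }
  score = s;
  mismatches = mm;
}

// [[Rcpp::export(name = ".cpp_align")]]
List cpp_align(SEXP xp, CharacterVector reads, int mismatch_pen, int n_pen) {
  XPtr<SeqIndex> idx(xp);
  R_xlen_t n = reads.size();
  IntegerVector out_t(n, NA_INTEGER), out_start(n, NA_INTEGER),
      out_as(n, NA_INTEGER), out_xs(n, NA_INTEGER), out_mm(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);
  std::vector<Cand> cands;
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    cands.clear();
    gather_candidates(*idx, fwd, 0, cands);
    gather_candidates(*idx, rev, 1, cands);
    if (cands.empty()) continue;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    int best_score = INT_MIN, best_mm = 0, second = INT_MIN;
    size_t best_i = 0;
    for (size_t i = 0; i < cands.size(); ++i) {
      const std::string& seq = cands[i].strand == 0 ? fwd : rev;
      int s, mm;
      score_ungapped(idx->seqs[cands[i].t], cands[i].start, seq,
                     mismatch_pen, n_pen, s, mm);
      // candidates are pre-sorted in tie-break order, so strict '>' keeps
      // the first (target, position, strand) among equals
      if (s > best_score) {
        if (best_score > second) second = best_score;
        best_score = s;
        best_mm = mm;
        best_i = i;
      } else if (s > second) {
        second = s;
      }
    }
    out_t[r] = cands[best_i].t + 1;
    out_start[r] = cands[best_i].start;
    out_strand[r] = cands[best_i].strand == 0 ? "+" : "-";
    out_as[r] = best_score;
    out_mm[r] = best_mm;
    if (second > INT_MIN) out_xs[r] = second;
  }
  return List::create(_["target"] = out_t, _["start"] = out_start,
                      _["strand"] = out_strand, _["AS"] = out_as,
                      _["XS"] = out_xs, _["mismatches"] = out_mm);
}

// Paired-consensus scoring for subgenome classification. consA/consB hold
// one entry per gene (same coordinate frame); an empty string marks a gene
// absent from that progenitor's consensus set. Columns where the read or
// either present consensus carries a non-ACGT character are excluded from
// both scores, so N stretches carry no assignment information.
// [[Rcpp::export(name = ".cpp_classify")]]
List cpp_classify(CharacterVector consA, CharacterVector consB,
                  CharacterVector reads, int k, int mismatch_pen) {
  if (consA.size() != consB.size())
    stop("consensus sets must be gene-aligned");
  R_xlen_t ng = consA.size();
  SeqIndex idx;
  idx.k = k;
  idx.n_positions = 0;
  std::vector<std::string> A(ng), B(ng);
  // index targets 0..ng-1 = side A, ng..2ng-1 = side B
  idx.seqs.reserve(2 * ng);
  for (R_xlen_t g = 0; g < ng; ++g) {
    A[g] = consA[g] == NA_STRING ? std::string() : as<std::string>(consA[g]);
    idx.seqs.push_back(A[g]);
    index_sequence(idx, A[g], (int32_t)g);
  }
  for (R_xlen_t g = 0; g < ng; ++g) {
    B[g] = consB[g] == NA_STRING ? std::string() : as<std::string>(consB[g]);
    idx.seqs.push_back(B[g]);
    index_sequence(idx, B[g], (int32_t)(ng + g));
  }
  R_xlen_t n = reads.size();
  IntegerVector out_g(n, NA_INTEGER), out_start(n, NA_INTEGER),
      out_sa(n, NA_INTEGER), out_sb(n, NA_INTEGER), out_ma(n, NA_INTEGER),
      out_mb(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);
  std::vector<Cand> cands;
  for (R_xlen_t r = 0; r < n; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp(fwd);
    cands.clear();
    gather_candidates(idx, fwd, 0, cands);
    gather_candidates(idx, rev, 1, cands);
    if (cands.empty()) continue;
    // collapse targets to genes
    for (size_t i = 0; i < cands.size(); ++i)
      if (cands[i].t >= ng) cands[i].t -= ng;
    std::sort(cands.begin(), cands.end());
    cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    int best_key = INT_MIN;
    int bsa = NA_INTEGER, bsb = NA_INTEGER, bma = NA_INTEGER,
        bmb = NA_INTEGER;
    size_t best_i = 0;
    bool found = false;
    for (size_t i = 0; i < cands.size(); ++i) {
      int g = cands[i].t;
      const std::string& a = A[g];
      const std::string& b = B[g];
      const std::string& seq = cands[i].strand == 0 ? fwd : rev;
      int64_t start = cands[i].start;
      int64_t L = (int64_t)seq.size();
      bool hasA = !a.empty(), hasB = !b.empty();
      if (hasA && start + L > (int64_t)a.size()) hasA = false;
      if (hasB && start + L > (int64_t)b.size()) hasB = false;
      if (!hasA && !hasB) continue;
      int sa = 0, sb = 0, ma = 0, mb = 0;
      for (int64_t p = 0; p < L; ++p) {
        int cr = base_code(seq[p]);
        int ca = hasA ? base_code(a[start + p]) : -1;
        int cb = hasB ? base_code(b[start + p]) : -1;
        bool masked = cr > 3 || (hasA && ca > 3) || (hasB && cb > 3);
        if (masked) continue;
        if (hasA && cr != ca) { sa -= mismatch_pen; ++ma; }
        if (hasB && cr != cb) { sb -= mismatch_pen; ++mb; }
      }
      int key;
      if (hasA && hasB) key = sa > sb ? sa : sb;
      else key = hasA ? sa : sb;
      if (!found || key > best_key) {
        found = true;
        best_key = key;
        best_i = i;
        bsa = hasA ? sa : NA_INTEGER;
        bsb = hasB ? sb : NA_INTEGER;
        bma = hasA ? ma : NA_INTEGER;
        bmb = hasB ? mb : NA_INTEGER;
      }
    }
    if (!found) continue;
    out_g[r] = cands[best_i].t + 1;
    out_start[r] = cands[best_i].start;
    out_strand[r] = cands[best_i].strand == 0 ? "+" : "-";
    out_sa[r] = bsa;
    out_sb[r] = bsb;
    out_ma[r] = bma;
    out_mb[r] = bmb;
  }
  return List::create(_["gene"] = out_g, _["start"] = out_start,
                      _["strand"] = out_strand, _["AS_A"] = out_sa,
                      _["AS_B"] = out_sb, _["mm_A"] = out_ma,
                      _["mm_B"] = out_mb);
}

// Base counts per target column. Reads must already be oriented to the
// target strand. Rows of each matrix: A, C, G, T, N.
// [[Rcpp::export(name = ".cpp_pileup")]]
List cpp_pileup(IntegerVector target_len, IntegerVector target,
                IntegerVector start, CharacterVector seqs) {
  int nt = target_len.size();
  std::vector<IntegerMatrix> mats;
  mats.reserve(nt);
  for (int t = 0; t < nt; ++t) mats.push_back(IntegerMatrix(5, target_len[t]));
  R_xlen_t n = target.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int t = target[i] - 1;
    if (t < 0 || t >= nt) stop("pileup: target index out of range");
    std::string s = as<std::string>(seqs[i]);
    int64_t p0 = start[i];
    if (p0 < 0 || p0 + (int64_t)s.size() > (int64_t)target_len[t])
      stop("pileup: alignment outside target bounds");
    IntegerMatrix& m = mats[t];
    for (size_t j = 0; j < s.size(); ++j) {
      int c = base_code(s[j]);
      m(c, p0 + j) += 1;
    }
  }
  List out(nt);
  for (int t = 0; t < nt; ++t) out[t] = mats[t];
  return out;
}

// Per-read kept range (1-based, inclusive) after trimming low-quality ends.
// If both = false only the 3' end is trimmed. end < start means discard all.
// [[Rcpp::export(name = ".cpp_trim_bounds")]]
IntegerMatrix cpp_trim_bounds(CharacterVector quals, int min_char, bool both) {
  R_xlen_t n = quals.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string q = as<std::string>(quals[i]);
    int64_t L = (int64_t)q.size();
    int64_t lo = 0, hi = L - 1;
    if (both) while (lo < L && (int)q[lo] < min_char) ++lo;
    while (hi >= lo && (int)q[hi] < min_char) --hi;
    out(i, 0) = (int)(lo + 1);
    out(i, 1) = (int)(hi + 1);
  }
  return out;
}
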