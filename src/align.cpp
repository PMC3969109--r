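// Seed-and-extend local alignment against a k-mer indexed transcript database.
//
// Seeds are exact word-length matches located through a hash index; each
// cluster of seeds on a subject defines a window in which a full
// Smith-Waterman alignment (affine gaps) of the whole read is computed, so
// that within a window the reported score equals the exhaustive local
// alignment score.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

struct SeedIndex {
  int word;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > > kmers;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int word) {
  SeedIndex *idx = new SeedIndex();
  idx->word = word;
  idx->seqs.reserve(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    idx->seqs.push_back(as<std::string>(seqs[i]));
  const uint64_t mask = (word >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * word)) - 1);
  for (size_t s = 0; s < idx->seqs.size(); ++s) {
    const std::string &sq = idx->seqs[s];
    if ((int)sq.size() < word) continue;  // zero seeds; caller warns
    uint64_t h = 0;
    int run = 0;  // valid (non-N) bases accumulated
    for (size_t p = 0; p < sq.size(); ++p) {
      int c = base_code(sq[p]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= word)
        idx->kmers[h].push_back(std::make_pair((int32_t)s, (int32_t)(p - word + 1)));
    }
  }
  XPtr<SeedIndex> ptr(idx, true);
  return ptr;
}

// Smith-Waterman of query vs subject window with affine gaps
// (gap of length L costs gap_open + gap_extend * L). Returns best local
// alignment with traceback statistics.
struct SWHit {
  int score, q_start, q_end, s_start, s_end;
  int matches, mismatches, gap_openings, aln_len;
};

static bool sw_align(const std::string &q, const std::string &s,
                     int win_lo, int win_hi,  // 0-based [lo, hi) in s
                     int match, int mismatch, int gap_open, int gap_extend,
                     SWHit &out) {
  const int n = (int)q.size();
  const int m = win_hi - win_lo;
  if (n == 0 || m <= 0) return false;
  const int W = m + 1;
  std::vector<int> H((n + 1) * W, 0), E((n + 1) * W, INT_MIN / 2), F((n + 1) * W, INT_MIN / 2);
  // traceback: 0 stop, 1 diag, 2 from E (gap in query: step left), 3 from F (gap in subject: step up)
  std::vector<uint8_t> TB((n + 1) * W, 0), TE((n + 1) * W, 0), TF((n + 1) * W, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int qi = base_code(q[i - 1]);
    for (int j = 1; j <= m; ++j) {
      int sj = base_code(s[win_lo + j - 1]);
      int idx = i * W + j;
      // E: gap in query (consume subject base), from left
      int openE = H[idx - 1] - gap_open - gap_extend;
      int extE = E[idx - 1] - gap_extend;
      E[idx] = std::max(openE, extE);
      TE[idx] = (uint8_t)(extE > openE ? 1 : 0);
      // F: gap in subject (consume query base), from above
      int openF = H[idx - W] - gap_open - gap_extend;
      int extF = F[idx - W] - gap_extend;
      F[idx] = std::max(openF, extF);
      TF[idx] = (uint8_t)(extF > openF ? 1 : 0);
      int sub = (qi >= 0 && sj >= 0 && qi == sj) ? match : mismatch;
      if (qi < 0 || sj < 0) sub = mismatch;  // N never matches
      int diag = H[idx - W - 1] + sub;
      int h = 0; uint8_t tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (E[idx] > h) { h = E[idx]; tb = 2; }
      if (F[idx] > h) { h = F[idx]; tb = 3; }
      H[idx] = h; TB[idx] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) return false;
  // traceback
  int i = bi, j = bj;
  int matches = 0, mism = 0, gaps = 0, alen = 0;
  int state = 0;  // 0 in H, 1 in E, 2 in F
  while (true) {
    int idx = i * W + j;
    if (state == 0) {
      uint8_t tb = TB[idx];
      if (tb == 0) break;
      if (tb == 1) {
        int qi = base_code(q[i - 1]), sj = base_code(s[win_lo + j - 1]);
        if (qi >= 0 && sj >= 0 && qi == sj) ++matches; else ++mism;
        ++alen; --i; --j;
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++alen;
      uint8_t te = TE[idx];
      --j;
      if (te == 0) { ++gaps; state = 0; }
    } else {
      ++alen;
      uint8_t tf = TF[idx];
      --i;
      if (tf == 0) { ++gaps; state = 0; }
    }
  }
  out.score = best;
  out.q_start = i + 1; out.q_end = bi;               // 1-based in query
  out.s_start = win_lo + j + 1; out.s_end = win_lo + bj;  // 1-based in subject
  out.matches = matches; out.mismatches = mism;
  out.gap_openings = gaps; out.aln_len = alen;
  return true;
}

struct RawHit {
  int query, subject, q_start, q_end, s_start, s_end;
  int score, mismatches, gap_openings, aln_len;
  double pct_identity;
  bool sense;
};

static void align_one_strand(const SeedIndex *idx, const std::string &read,
                             int query_no, bool sense, int read_len_orig,
                             int match, int mismatch, int gap_open, int gap_extend,
                             int min_score, std::vector<RawHit> &hits) {
  const int word = idx->word;
  const int n = (int)read.size();
  if (n < word) return;
  const uint64_t mask = (word >= 32) ? ~uint64_t(0) : ((uint64_t(1) << (2 * word)) - 1);
  // collect seed subject positions per subject
  std::unordered_map<int, std::vector<int> > seeds;
  uint64_t h = 0; int run = 0;
  for (int p = 0; p < n; ++p) {
    int c = base_code(read[p]);
    if (c < 0) { run = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t)c) & mask;
    if (++run >= word) {
      std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t> > >::const_iterator it = idx->kmers.find(h);
      if (it != idx->kmers.end())
        for (size_t k = 0; k < it->second.size(); ++k)
          seeds[it->second[k].first].push_back(it->second[k].second);
    }
  }
  for (std::unordered_map<int, std::vector<int> >::iterator it = seeds.begin(); it != seeds.end(); ++it) {
    int subj = it->first;
    std::vector<int> &pos = it->second;
    std::sort(pos.begin(), pos.end());
    const std::string &sseq = idx->seqs[subj];
    const int slen = (int)sseq.size();
    size_t a = 0;
    while (a < pos.size()) {
      size_t b = a;
      while (b + 1 < pos.size() && pos[b + 1] - pos[b] <= n) ++b;
      int lo = std::max(0, pos[a] - n - 8);
      int hi = std::min(slen, pos[b] + word + n + 8);
      SWHit sw;
      if (sw_align(read, sseq, lo, hi, match, mismatch, gap_open, gap_extend, sw) &&
          sw.score >= min_score) {
        RawHit rh;
        rh.query = query_no; rh.subject = subj + 1;
        rh.score = sw.score; rh.mismatches = sw.mismatches;
        rh.gap_openings = sw.gap_openings; rh.aln_len = sw.aln_len;
        rh.pct_identity = 100.0 * sw.matches / (double)sw.aln_len;
        rh.sense = sense;
        if (sense) {
          rh.q_start = sw.q_start; rh.q_end = sw.q_end;
          rh.s_start = sw.s_start; rh.s_end = sw.s_end;
        } else {
          // read was reverse-complemented: map back to original read coords,
          // subject coordinates reported descending (antisense)
          rh.q_start = read_len_orig - sw.q_end + 1;
          rh.q_end = read_len_orig - sw.q_start + 1;
          rh.s_start = sw.s_end; rh.s_end = sw.s_start;
        }
        hits.push_back(rh);
      }
      a = b + 1;
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_local_align(SEXP index_ptr, CharacterVector reads,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int min_score, bool both_strands) {
  XPtr<SeedIndex> idx(index_ptr);
  std::vector<RawHit> hits;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    int L = (int)read.size();
    align_one_strand(idx, read, (int)r + 1, true, L, match, mismatch,
                     gap_open, gap_extend, min_score, hits);
    if (both_strands) {
      std::string rc(read.rbegin(), read.rend());
      for (size_t i = 0; i < rc.size(); ++i) rc[i] = comp_base(rc[i]);
      align_one_strand(idx, rc, (int)r + 1, false, L, match, mismatch,
                       gap_open, gap_extend, min_score, hits);
    }
  }
  // deduplicate identical placements (windows may overlap)
  std::sort(hits.begin(), hits.end(), [](const RawHit &x, const RawHit &y) {
    if (x.query != y.query) return x.query < y.query;
    if (x.subject != y.subject) return x.subject < y.subject;
    if (x.q_start != y.q_start) return x.q_start < y.q_start;
    if (x.q_end != y.q_end) return x.q_end < y.q_end;
    if (x.s_start != y.s_start) return x.s_start < y.s_start;
    if (x.s_end != y.s_end) return x.s_end < y.s_end;
    return x.score > y.score;
  });
  std::vector<RawHit> uniq;
  for (size_t i = 0; i < hits.size(); ++i) {
    if (!uniq.empty()) {
      const RawHit &u = uniq.back(), &h = hits[i];
      if (u.query == h.query && u.subject == h.subject && u.q_start == h.q_start &&
          u.q_end == h.q_end && u.s_start == h.s_start && u.s_end == h.s_end)
        continue;
    }
    uniq.push_back(hits[i]);
  }
  const size_t nh = uniq.size();
  IntegerVector query(nh), subject(nh), q_start(nh), q_end(nh), s_start(nh),
      s_end(nh), score(nh), mism(nh), gaps(nh), alen(nh);
  NumericVector pid(nh);
  for (size_t i = 0; i < nh; ++i) {
    query[i] = uniq[i].query; subject[i] = uniq[i].subject;
    q_start[i] = uniq[i].q_start; q_end[i] = uniq[i].q_end;
    s_start[i] = uniq[i].s_start; s_end[i] = uniq[i].s_end;
    score[i] = uniq[i].score; mism[i] = uniq[i].mismatches;
    gaps[i] = uniq[i].gap_openings; alen[i] = uniq[i].aln_len;
    pid[i] = uniq[i].pct_identity;
  }
  return DataFrame::create(
      _["query"] = query, _["subject"] = subject,
      _["pct_identity"] = pid, _["aln_len"] = alen,
      _["mismatches"] = mism, _["gap_openings"] = gaps,
      _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end,
      _["score"] = score);
}

// [[Rcpp::export]]
int cpp_index_word(SEXP index_ptr) {
  XPtr<SeedIndex> idx(index_ptr);
  return idx->word;
}

// 3' adapter trimming: returns kept read length after removing the longest
// qualifying adapter match (full internal occurrence, or a read suffix
// matching an adapter prefix of length >= min_match with <= floor(k/10)
// mismatches).
// [[Rcpp::export]]
IntegerVector cpp_trim_adapter(CharacterVector seqs, std::string adapter, int min_match) {
  const int alen = (int)adapter.size();
  IntegerVector keep(seqs.size());
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int n = (int)s.size();
    int kept = n;
    if (min_match > 0) {
      // full internal adapter occurrence (exact): cut adapter and all 3' of it
      size_t at = s.find(adapter);
      if (at != std::string::npos) {
        kept = (int)at;
      } else {
        for (int k = std::min(n, alen); k >= min_match; --k) {
          int mm = 0, allowed = k / 10;
          const char *sfx = s.c_str() + (n - k);
          for (int i = 0; i < k; ++i)
            if (sfx[i] != adapter[i] && ++mm > allowed) break;
          if (mm <= allowed) { kept = n - k; break; }
        }
      }
    }
    keep[r] = kept;
  }
  return keep;
}
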