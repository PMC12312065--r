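#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static const int NEG = -1000000000;

// Glocal alignment: query is consumed end-to-end (global in the read),
// reference prefix/suffix are free (local in the window).
// Affine gaps: the first gapped base costs `gap_open`, each further base
// `gap_extend`.  Ties are resolved by a fixed operation preference
// (diagonal, then deletion, then insertion) and, for the end column, by
// the smallest reference end position, which together with the traceback
// order yields the leftmost-start / deletion-before-insertion contract.
//
// Returns list(score, ref_start (0-based), ref_row, read_row), where the
// two rows are equal-length padded strings ('-' marks a gap).
// [[Rcpp::export]]
List cpp_glocal_align(std::string query, std::string ref,
                      int match, int mismatch, int gap_open, int gap_extend) {
  int m = (int) query.size(), n = (int) ref.size();
  if (m == 0) stop("empty query");
  if (n == 0) stop("empty reference");

  // DP over query rows i=0..m, ref cols j=0..n.
  // M: last op consumes both; D: gap in read (ref base deleted from read);
  // I: gap in ref (read base inserted).
  std::vector<int> M((m + 1) * (n + 1), NEG), D((m + 1) * (n + 1), NEG),
      I((m + 1) * (n + 1), NEG);
  auto ix = [n](int i, int j) { return i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) M[ix(0, j)] = 0;  // free start anywhere in ref
  for (int i = 1; i <= m; ++i) {
    // leading insertion (query bases before touching the reference)
    I[ix(i, 0)] = gap_open + (i - 1) * gap_extend;
    const char qc = query[i - 1];
    for (int j = 1; j <= n; ++j) {
      const int s = (qc == ref[j - 1]) ? match : mismatch;
      int best = M[ix(i - 1, j - 1)];
      if (D[ix(i - 1, j - 1)] > best) best = D[ix(i - 1, j - 1)];
      if (I[ix(i - 1, j - 1)] > best) best = I[ix(i - 1, j - 1)];
      M[ix(i, j)] = (best <= NEG / 2) ? NEG : best + s;

      int dM = M[ix(i, j - 1)] <= NEG / 2 ? NEG : M[ix(i, j - 1)] + gap_open;
      int dD = D[ix(i, j - 1)] <= NEG / 2 ? NEG : D[ix(i, j - 1)] + gap_extend;
      int dI = I[ix(i, j - 1)] <= NEG / 2 ? NEG : I[ix(i, j - 1)] + gap_open;
      D[ix(i, j)] = std::max(dM, std::max(dD, dI));

      int iM = M[ix(i - 1, j)] <= NEG / 2 ? NEG : M[ix(i - 1, j)] + gap_open;
      int iI = I[ix(i - 1, j)] <= NEG / 2 ? NEG : I[ix(i - 1, j)] + gap_extend;
      int iD = D[ix(i - 1, j)] <= NEG / 2 ? NEG : D[ix(i - 1, j)] + gap_open;
      I[ix(i, j)] = std::max(iM, std::max(iI, iD));
    }
  }

  // Free ref suffix: best cell in the last query row, M or I state
  // (ending in a read-gap D would be pointless with a free suffix).
  int bestScore = NEG, bestJ = -1; char bestState = 'M';
  for (int j = 0; j <= n; ++j) {
    int sm = M[ix(m, j)], si = I[ix(m, j)];
    if (sm > bestScore) { bestScore = sm; bestJ = j; bestState = 'M'; }
    if (si > bestScore) { bestScore = si; bestJ = j; bestState = 'I'; }
  }

  // Traceback.
  std::string refRow, readRow;
  int i = m, j = bestJ; char st = bestState;
  while (i > 0) {
    if (st == 'M') {
      refRow.push_back(ref[j - 1]);
      readRow.push_back(query[i - 1]);
      const int cur = M[ix(i, j)];
      const int s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      --i; --j;
      if (M[ix(i, j)] + s == cur) st = 'M';
      else if (D[ix(i, j)] + s == cur) st = 'D';
      else st = 'I';
      if (i == 0) break;
    } else if (st == 'D') {
      refRow.push_back(ref[j - 1]);
      readRow.push_back('-');
      const int cur = D[ix(i, j)];
      --j;
      if (M[ix(i, j)] + gap_open == cur) st = 'M';
      else if (D[ix(i, j)] + gap_extend == cur) st = 'D';
      else st = 'I';
    } else {  // I
      refRow.push_back('-');
      readRow.push_back(query[i - 1]);
      const int cur = I[ix(i, j)];
      --i;
      if (i == 0) break;
      if (M[ix(i, j)] + gap_open == cur) st = 'M';
      else if (I[ix(i, j)] + gap_extend == cur) st = 'I';
      else st = 'D';
    }
  }
  std::reverse(refRow.begin(), refRow.end());
  std::reverse(readRow.begin(), readRow.end());
  return List::create(_["score"] = bestScore, _["ref_start"] = j,
                      _["ref_row"] = refRow, _["read_row"] = readRow);
}

// Per-column plurality consensus of equal-length strings.
// A base is kept when its fraction of the column depth is >= threshold,
// otherwise the column becomes 'N'.  Exact count ties below threshold give
// 'N'; at or above threshold the lexicographically smallest top base wins
// (unreachable with threshold > 0.5).
static std::string consensus_one(const std::vector<const char*>& seqs,
                                 size_t len, double threshold) {
  std::string out(len, 'N');
  const size_t nseq = seqs.size();
  if (nseq == 1) { out.assign(seqs[0], len); return out; }
  for (size_t p = 0; p < len; ++p) {
    int cnt[5] = {0, 0, 0, 0, 0};  // A C G T other/N
    for (size_t s = 0; s < nseq; ++s) {
      switch (seqs[s][p]) {
        case 'A': ++cnt[0]; break;
        case 'C': ++cnt[1]; break;
        case 'G': ++cnt[2]; break;
        case 'T': ++cnt[3]; break;
        default: ++cnt[4];
      }
    }
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    int best = -1, bestCnt = 0;
    for (int b = 0; b < 4; ++b)
      if (cnt[b] > bestCnt) { bestCnt = cnt[b]; best = b; }
    if (best >= 0 && (double) bestCnt / (double) nseq >= threshold)
      out[p] = bases[best];
  }
  return out;
}

// [[Rcpp::export]]
std::string cpp_consensus_strings(CharacterVector seqs, double threshold) {
  if (seqs.size() == 0) stop("no sequences");
  size_t len = std::strlen(CHAR(STRING_ELT(seqs, 0)));
  std::vector<const char*> ptr(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if (std::strlen(s) != len) stop("sequences differ in length");
    ptr[i] = s;
  }
  return consensus_one(ptr, len, threshold);
}

// Batch plurality consensus over runs of equal group id (input must be
// sorted by group).  Returns one consensus string per run.
// [[Rcpp::export]]
List cpp_consensus_by_group(CharacterVector seqs, IntegerVector group,
                            double threshold) {
  R_xlen_t n = seqs.size();
  if (n != group.size()) stop("length mismatch");
  std::vector<std::string> cons;
  std::vector<int> gid;
  std::vector<int> depth;
  R_xlen_t i = 0;
  while (i < n) {
    R_xlen_t j = i;
    while (j < n && group[j] == group[i]) ++j;
    size_t len = std::strlen(CHAR(STRING_ELT(seqs, i)));
    std::vector<const char*> ptr;
    ptr.reserve(j - i);
    for (R_xlen_t k = i; k < j; ++k) {
      const char* s = CHAR(STRING_ELT(seqs, k));
      if (std::strlen(s) != len) stop("sequences differ in length within group");
      ptr.push_back(s);
    }
    cons.push_back(consensus_one(ptr, len, threshold));
    gid.push_back(group[i]);
    depth.push_back((int) (j - i));
    i = j;
  }
  return List::create(_["group"] = wrap(gid), _["consensus"] = wrap(cons),
                      _["n_reads"] = wrap(depth));
}

// --- padded-alignment merging -------------------------------------------
// A padded alignment is (ref_start, ref_row, read_row): equal-length rows,
// '-' in ref_row marks an insertion column (attached after the preceding
// reference position), '-' in read_row marks a deleted reference base.

struct Seg {             // one reference position worth of alignment
  char base;             // read state at this ref position ('-' = deleted)
  std::string ins;       // read bases inserted AFTER this ref position
};

static void parse_padded(int start, const char* refRow, const char* readRow,
                         std::map<int, Seg>& segs) {
  int pos = start - 1;  // last consumed ref position
  size_t L = std::strlen(refRow);
  for (size_t c = 0; c < L; ++c) {
    if (refRow[c] == '-') {
      if (pos >= start) segs[pos].ins.push_back(readRow[c]);
      // leading insertions (before the first ref column) are dropped
    } else {
      ++pos;
      Seg s; s.base = readRow[c]; segs[pos] = s;
    }
  }
}

static List emit_padded(const std::map<int, Seg>& segs) {
  if (segs.empty())
    return List::create(_["ref_start"] = NA_INTEGER, _["ref_row"] = "",
                        _["read_row"] = "");
  std::string refRow, readRow;
  int start = segs.begin()->first;
  for (auto& kv : segs) {
    refRow.push_back('R');  // placeholder, caller restores reference chars
    readRow.push_back(kv.second.base);
    for (char b : kv.second.ins) { refRow.push_back('-'); readRow.push_back(b); }
  }
  return List::create(_["ref_start"] = start, _["ref_row"] = refRow,
                      _["read_row"] = readRow);
}

// Merge two padded alignments of the same reference.
// mode 0 (mate merge): union of spans; overlap disagreement -> 'N',
//   insertion kept only when both members having coverage agree on it.
// mode 1 (duplex merge): intersection of spans; disagreement (including one
//   side 'N') -> 'N'; insertion kept only when identical on both strands.
// [[Rcpp::export]]
List cpp_merge_padded(int start1, std::string refRow1, std::string readRow1,
                      int start2, std::string refRow2, std::string readRow2,
                      int mode) {
  std::map<int, Seg> a, b;
  parse_padded(start1, refRow1.c_str(), readRow1.c_str(), a);
  parse_padded(start2, refRow2.c_str(), readRow2.c_str(), b);
  std::map<int, Seg> out;
  if (mode == 1) {
    for (auto& kv : a) {
      auto it = b.find(kv.first);
      if (it == b.end()) continue;
      Seg s;
      s.base = (kv.second.base == it->second.base) ? kv.second.base : 'N';
      if (kv.second.ins == it->second.ins) s.ins = kv.second.ins;
      out[kv.first] = s;
    }
  } else {
    for (auto& kv : a) out[kv.first] = kv.second;
    for (auto& kv : b) {
      auto it = out.find(kv.first);
      if (it == out.end()) { out[kv.first] = kv.second; continue; }
      if (it->second.base != kv.second.base) it->second.base = 'N';
      if (it->second.ins != kv.second.ins) it->second.ins.clear();
    }
  }
  return emit_padded(out);
}

// Extract variant observations from padded alignments against the window
// sequence.  Positions are 0-based window coordinates.  Runs of adjacent
// deleted columns merge into one deletion; insertion columns yield one
// insertion per slot (skipped when any inserted base is 'N'); 'N' read
// columns yield nothing.  Observations whose ref-coordinate footprint lies
// within `edge_guard` columns of the covered span are discarded.
// Also returns the per-alignment span and every 'N' column position
// (needed for non-N depth accounting).
// [[Rcpp::export]]
List cpp_extract_observations(IntegerVector starts, CharacterVector refRows,
                              CharacterVector readRows, std::string window,
                              int edge_guard) {
  std::vector<int> o_idx, o_pos; std::vector<std::string> o_ref, o_alt;
  std::vector<std::string> o_kind;
  std::vector<int> n_idx, n_pos;
  std::vector<int> span_start(starts.size()), span_end(starts.size());

  for (R_xlen_t r = 0; r < starts.size(); ++r) {
    const char* refRow = CHAR(STRING_ELT(refRows, r));
    const char* readRow = CHAR(STRING_ELT(readRows, r));
    size_t L = std::strlen(refRow);
    int start = starts[r];
    // span in ref coordinates
    int span = 0;
    for (size_t c = 0; c < L; ++c) if (refRow[c] != '-') ++span;
    span_start[r] = start; span_end[r] = start + span;
    const int lo = start + edge_guard, hi = start + span - edge_guard; // [lo,hi)

    int pos = start - 1;
    int del_start = -1; std::string del_ref;
    std::string ins; int ins_after = -1;
    auto flush_del = [&](void) {
      if (del_start >= 0) {
        if (del_start >= lo && (del_start + (int) del_ref.size()) <= hi) {
          o_idx.push_back((int) r + 1); o_pos.push_back(del_start);
          o_ref.push_back(del_ref); o_alt.push_back("");
          o_kind.push_back("deletion");
        }
        del_start = -1; del_ref.clear();
      }
    };
    auto flush_ins = [&](void) {
      if (ins_after >= 0 && !ins.empty()) {
        int at = ins_after + 1;  // inserted before this coordinate
        if (ins.find('N') == std::string::npos && at > lo && at < hi) {
          o_idx.push_back((int) r + 1); o_pos.push_back(at);
          o_ref.push_back(""); o_alt.push_back(ins);
          o_kind.push_back("insertion");
        }
      }
      ins_after = -1; ins.clear();
    };
    for (size_t c = 0; c < L; ++c) {
      if (refRow[c] == '-') {               // insertion column
        if (pos >= start) { if (ins_after < 0) ins_after = pos; ins.push_back(readRow[c]); }
        continue;
      }
      ++pos;
      flush_ins();
      char rb = (pos < (int) window.size()) ? window[pos] : 'N';
      char qb = readRow[c];
      if (qb == '-') {
        if (del_start < 0) del_start = pos;
        del_ref.push_back(rb);
        continue;
      }
      flush_del();
      if (qb == 'N') { n_idx.push_back((int) r + 1); n_pos.push_back(pos); continue; }
      if (qb != rb && pos >= lo && pos < hi) {
        o_idx.push_back((int) r + 1); o_pos.push_back(pos);
        o_ref.push_back(std::string(1, rb)); o_alt.push_back(std::string(1, qb));
        o_kind.push_back("SNV");
      }
    }
    flush_del(); flush_ins();
  }
  return List::create(
      _["obs"] = DataFrame::create(_["idx"] = wrap(o_idx), _["pos"] = wrap(o_pos),
                                   _["ref"] = wrap(o_ref), _["alt"] = wrap(o_alt),
                                   _["kind"] = wrap(o_kind),
                                   _["stringsAsFactors"] = false),
      _["n_cols"] = DataFrame::create(_["idx"] = wrap(n_idx), _["pos"] = wrap(n_pos)),
      _["span_start"] = wrap(span_start), _["span_end"] = wrap(span_end));
}

// Apply point substitutions to strings in place (1-based read index and
// position).  Duplicate (idx, pos) entries are applied sequentially, the
// last one wins.
// [[Rcpp::export]]
CharacterVector cpp_substitute(CharacterVector seqs, IntegerVector idx,
                               IntegerVector pos, CharacterVector base) {
  CharacterVector out = clone(seqs);
  std::map<int, std::string> touched;
  for (R_xlen_t k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    auto it = touched.find(i);
    if (it == touched.end())
      it = touched.emplace(i, std::string(CHAR(STRING_ELT(out, i)))).first;
    int p = pos[k] - 1;
    if (p < 0 || p >= (int) it->second.size()) stop("position out of range");
    it->second[p] = CHAR(STRING_ELT(base, k))[0];
  }
  for (auto& kv : touched) out[kv.first] = kv.second;
  return out;
}

// Mean Phred quality (offset 33) per quality string.
// [[Rcpp::export]]
NumericVector cpp_mean_phred(CharacterVector quals) {
  NumericVector out(quals.size());
  for (R_xlen_t i = 0; i < quals.size(); ++i) {
    const char* q = CHAR(STRING_ELT(quals, i));
    size_t L = std::strlen(q);
    long s = 0;
    for (size_t c = 0; c < L; ++c) s += q[c] - 33;
    out[i] = L ? (double) s / (double) L : NA_REAL;
  }
  return out;
}

// Hamming distance between equal-length prefixes of `seqs` and `pattern`
// (NA when a sequence is shorter than the pattern).
// [[Rcpp::export]]
IntegerVector cpp_prefix_mismatches(CharacterVector seqs, std::string pattern) {
  IntegerVector out(seqs.size());
  size_t pl = pattern.size();
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    if (std::strlen(s) < pl) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t c = 0; c < pl; ++c) if (s[c] != pattern[c]) ++d;
    out[i] = d;
  }
  return out;
}
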