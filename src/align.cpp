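#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Semi-global DNA alignment with linear gap costs.
//
// Two end-gap policies:
//  * "overlap":      terminal gaps free on both ends of both sequences
//                    (SortMeRNA-like screen; coverage of the query can be < 1).
//  * "query_global": the full query must be aligned (query terminal gaps are
//                    penalised); reference terminal gaps are free. This is the
//                    usearch/vsearch-style global-query alignment used for
//                    taxonomy search, where identity is computed over the whole
//                    query and coverage is 1 by construction.
//
// Identity = matches / alignment columns, where the columns are those on the
// traceback path (terminal overhangs excluded). Internal gap columns count in
// the denominator. A match is an IUPAC set intersection.

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'U': return 8;
    case 'M': return 1|2; case 'R': return 1|4; case 'W': return 1|8;
    case 'S': return 2|4; case 'Y': return 2|8; case 'K': return 4|8;
    case 'V': return 1|2|4; case 'H': return 1|2|8; case 'D': return 1|4|8;
    case 'B': return 2|4|8; case 'N': return 15;
    default:  return 0;  // never matches anything
  }
}

struct AlnResult {
  int score, matches, columns, q_start, q_end;
  double identity, coverage;
};

// DP over rows = query, cols = reference; integer scores, rolling rows for
// the score matrix, full (byte) traceback matrix.
static AlnResult align_one(const std::string& q, const std::vector<int>& rmask,
                           const std::vector<int>& qmask,
                           bool query_global, int match, int mismatch, int gap) {
  const int n = (int) qmask.size(), m = (int) rmask.size();
  const int NEG = -1 << 28;
  std::vector<int> prev(m + 1), curr(m + 1), last_col(n + 1);
  std::vector<unsigned char> T((size_t)(n + 1) * (m + 1));
  const size_t W = m + 1;

  prev[0] = 0;
  for (int j = 1; j <= m; ++j) { prev[j] = 0; T[j] = 2; }  // ref prefix free
  last_col[0] = prev[m];
  for (int i = 1; i <= n; ++i) {
    curr[0] = query_global ? i * gap : 0;
    T[i * W] = 1;
    const int qmi = qmask[i - 1];
    unsigned char* Ti = &T[i * W];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + (((qmi & rmask[j - 1]) != 0) ? match : mismatch);
      int u = prev[j] + gap;
      int l = curr[j - 1] + gap;
      int best = d; unsigned char tb = 0;
      if (u > best) { best = u; tb = 1; }
      if (l > best) { best = l; tb = 2; }
      curr[j] = best; Ti[j] = tb;
    }
    last_col[i] = curr[m];
    std::swap(prev, curr);
  }
  // after the swap, `prev` holds the last row (i = n)
  int ei = n, ej = m, best = prev[m];
  for (int j = 0; j <= m; ++j)                 // ref suffix free (both modes)
    if (prev[j] > best) { best = prev[j]; ei = n; ej = j; }
  if (!query_global) {                         // query suffix also free
    for (int i = 0; i <= n; ++i)
      if (last_col[i] > best) { best = last_col[i]; ei = i; ej = m; }
  }
  (void) NEG;

  int i = ei, j = ej, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    if (j == 0) {
      if (!query_global) break;
      --i; ++columns;                          // penalised query-prefix column
      continue;
    }
    if (i == 0) break;                         // free ref-prefix overhang
    unsigned char tb = T[(size_t) i * W + j];
    if (tb == 0) {
      if ((qmask[i - 1] & rmask[j - 1]) != 0) ++matches;
      --i; --j; ++columns;
    } else if (tb == 1) {
      --i; ++columns;
    } else {
      --j; ++columns;
    }
  }
  AlnResult res;
  res.score = best;
  res.matches = matches;
  res.columns = columns;
  res.q_start = i + 1;
  res.q_end = ei;
  res.identity = columns > 0 ? (double) matches / columns : 0.0;
  res.coverage = query_global ? 1.0
    : (res.q_end >= res.q_start ? (double) (res.q_end - res.q_start + 1) / n : 0.0);
  return res;
}

// [[Rcpp::export(name = ".align_batch_cpp")]]
DataFrame align_batch_cpp(std::string query, CharacterVector refs,
                          bool query_global,
                          int match, int mismatch, int gap) {
  const int nr = refs.size();
  std::vector<int> qmask(query.size());
  for (size_t i = 0; i < query.size(); ++i) qmask[i] = iupac_mask(query[i]);
  NumericVector score(nr), identity(nr), coverage(nr);
  IntegerVector matches(nr), columns(nr), q_start(nr), q_end(nr);
  std::vector<int> rmask;
  for (int k = 0; k < nr; ++k) {
    std::string r = as<std::string>(refs[k]);
    rmask.assign(r.size(), 0);
    for (size_t i = 0; i < r.size(); ++i) rmask[i] = iupac_mask(r[i]);
    AlnResult a = align_one(query, rmask, qmask, query_global,
                            match, mismatch, gap);
    score[k] = a.score; identity[k] = a.identity; coverage[k] = a.coverage;
    matches[k] = a.matches; columns[k] = a.columns;
    q_start[k] = a.q_start; q_end[k] = a.q_end;
  }
  return DataFrame::create(_["score"] = score, _["identity"] = identity,
                           _["coverage"] = coverage, _["matches"] = matches,
                           _["columns"] = columns, _["q_start"] = q_start,
                           _["q_end"] = q_end);
}

// Sorted unique k-mer codes (2 bits per base; windows containing non-ACGT
// letters are skipped) for each sequence. Used by the shared-k-mer prefilter.
// [[Rcpp::export(name = ".kmer_code_sets_cpp")]]
List kmer_code_sets_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 15) stop("k must be in 1..15");
  List out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    std::string x = as<std::string>(seqs[s]);
    std::vector<int> codes;
    int code = 0, valid = 0;
    const int mask = (1 << (2 * k)) - 1;
    for (size_t i = 0; i < x.size(); ++i) {
      int b;
      switch (x[i]) {
        case 'A': b = 0; break; case 'C': b = 1; break;
        case 'G': b = 2; break; case 'T': b = 3; break;
        default: b = -1;
      }
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & mask;
      if (++valid >= k) codes.push_back(code);
    }
    std::sort(codes.begin(), codes.end());
    codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    out[s] = IntegerVector(codes.begin(), codes.end());
  }
  return out;
}

// Count of shared distinct k-mer codes between the query's sorted code set
// and each reference's sorted code set (two-pointer intersections).
// [[Rcpp::export(name = ".shared_kmer_counts_cpp")]]
IntegerVector shared_kmer_counts_cpp(IntegerVector query_codes, List ref_codes) {
  const int nr = ref_codes.size();
  IntegerVector out(nr);
  for (int r = 0; r < nr; ++r) {
    IntegerVector rc = ref_codes[r];
    int i = 0, j = 0, shared = 0;
    while (i < query_codes.size() && j < rc.size()) {
      if (query_codes[i] < rc[j]) ++i;
      else if (query_codes[i] > rc[j]) ++j;
      else { ++shared; ++i; ++j; }
    }
    out[r] = shared;
  }
  return out;
}
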