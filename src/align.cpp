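#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Ends-free (overlap) pairwise alignment with linear gap costs.
//
// Cell value is the lexicographic maximum of (score, matches, qcore, -cols)
// over all paths, where qcore counts query bases inside the aligned core and
// cols counts aligned columns (match + mismatch + interior gap columns).
// Lexicographic maximisation with constant per-move increments is associative,
// so a value-only DP suffices; no traceback is needed and the reported
// identity / coverage are uniquely defined.
struct Cell {
  long score;
  long matches;
  long qcore;
  long cols;
};

static inline bool lex_less(const Cell &a, const Cell &b) {
  if (a.score != b.score) return a.score < b.score;
  if (a.matches != b.matches) return a.matches < b.matches;
  if (a.qcore != b.qcore) return a.qcore < b.qcore;
  return a.cols > b.cols; // fewer columns preferred
}

// [[Rcpp::export]]
List semi_global_align_cpp(std::string q, std::string r,
                           int match = 1, int mismatch = -1, int gap = -2) {
  const long m = (long)q.size();
  const long n = (long)r.size();
  if (m == 0 || n == 0)
    stop("both sequences must be non-empty");

  std::vector<Cell> prev(n + 1), cur(n + 1);
  for (long j = 0; j <= n; ++j) prev[j] = {0, 0, 0, 0}; // free leading ref
  Cell best = {0, 0, 0, 0};

  for (long i = 1; i <= m; ++i) {
    cur[0] = {0, 0, 0, 0}; // free leading query
    const char qc = q[i - 1];
    for (long j = 1; j <= n; ++j) {
      const bool eq = (qc == r[j - 1]);
      Cell d = prev[j - 1];
      d.score += eq ? match : mismatch;
      d.matches += eq ? 1 : 0;
      d.qcore += 1;
      d.cols += 1;
      Cell u = prev[j];
      u.score += gap; u.qcore += 1; u.cols += 1;
      Cell l = cur[j - 1];
      l.score += gap; l.cols += 1;
      Cell v = d;
      if (lex_less(v, u)) v = u;
      if (lex_less(v, l)) v = l;
      cur[j] = v;
    }
    if (lex_less(best, cur[n])) best = cur[n]; // free trailing query
    std::swap(prev, cur);
  }
  for (long j = 0; j <= n; ++j)
    if (lex_less(best, prev[j])) best = prev[j]; // free trailing ref

  const double identity =
      best.cols > 0 ? 100.0 * (double)best.matches / (double)best.cols : 0.0;
  const double coverage = 100.0 * (double)best.qcore / (double)m;
  return List::create(_["identity"] = identity,
                      _["query_coverage"] = coverage,
                      _["score"] = (double)best.score,
                      _["matches"] = (double)best.matches,
                      _["columns"] = (double)best.cols);
}

// Scan candidate terminal-overlap lengths from longest to shortest; a
// candidate L succeeds when the Hamming mismatch count between the first and
// last L bases is <= floor(max_mismatch_frac * L). First success wins.
// [[Rcpp::export]]
List terminal_overlap_cpp(std::string s, int min_overlap, int max_overlap,
                          double max_mismatch_frac) {
  const long len = (long)s.size();
  long hi = std::min((long)max_overlap, len / 2);
  for (long L = hi; L >= (long)min_overlap; --L) {
    const long allowed = (long)std::floor(max_mismatch_frac * (double)L);
    long mm = 0;
    const char *a = s.data();
    const char *b = s.data() + (len - L);
    bool ok = true;
    for (long k = 0; k < L; ++k) {
      if (a[k] != b[k] && ++mm > allowed) { ok = false; break; }
    }
    if (ok)
      return List::create(_["overlap_len"] = (double)L,
                          _["mismatches"] = (double)mm);
  }
  return List::create(_["overlap_len"] = 0.0, _["mismatches"] = NA_REAL);
}
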