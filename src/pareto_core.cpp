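#include <Rcpp.h>
using namespace Rcpp;

// Does row j strictly (or weakly) dominate row i in the first n rows of F?
// Early exit on the first objective where j is worse than i.
static inline bool dominates_rows(const NumericMatrix& F, int j, int i, bool weak) {
  const int m = F.ncol();
  bool strictly_better = false;
  for (int k = 0; k < m; ++k) {
    const double fj = F(j, k), fi = F(i, k);
    if (fj > fi) return false;
    if (fj < fi) strictly_better = true;
  }
  return weak || strictly_better;
}

// [[Rcpp::export]]
bool cpp_strictly_dominates(const NumericVector& fj, const NumericVector& fi) {
  const int m = fj.size();
  bool strictly_better = false;
  for (int k = 0; k < m; ++k) {
    if (fj[k] > fi[k]) return false;   // early exit: j worse somewhere
    if (fj[k] < fi[k]) strictly_better = true;
  }
  return strictly_better;
}

// Dominance-count ranks of the first n_used rows (n_used < 0 => all rows).
// O(n^2 m) pairwise scan; deterministic regardless of record order.
// [[Rcpp::export]]
IntegerVector cpp_rank_all(const NumericMatrix& F, bool weak = false,
                           int n_used = -1) {
  const int n = (n_used < 0) ? F.nrow() : n_used;
  IntegerVector r(n);
  for (int i = 0; i < n; ++i) {
    int ri = 0;
    for (int j = 0; j < n; ++j) {
      if (j != i && dominates_rows(F, j, i, weak)) ++ri;
    }
    r[i] = ri;
  }
  return r;
}

// Single O(nm) pass testing dominance in both directions between a candidate
// objective vector and the first n rows of F. Returns the 1-based indices of
// existing records the candidate strictly dominates ("touched", whose ranks
// must be incremented) and the candidate's own dominance-count rank.
// [[Rcpp::export]]
List cpp_insert_scan(const NumericMatrix& F, int n, const NumericVector& fnew) {
  const int m = F.ncol();
  std::vector<int> touched;
  int cand_rank = 0;
  for (int i = 0; i < n; ++i) {
    bool new_le = true, new_lt = false;  // candidate vs record i
    bool old_le = true, old_lt = false;  // record i vs candidate
    for (int k = 0; k < m; ++k) {
      const double a = fnew[k], b = F(i, k);
      if (a > b) { new_le = false; old_lt = true; }
      else if (a < b) { new_lt = true; old_le = false; }
      if (!new_le && !old_le) break;
    }
    if (new_le && new_lt) touched.push_back(i + 1);
    if (old_le && old_lt) ++cand_rank;
  }
  return List::create(_["touched"] = wrap(touched),
                      _["candidate_rank"] = cand_rank);
}

// Number of the first n rows of F that strictly dominate f.
// [[Rcpp::export]]
int cpp_count_dominators(const NumericMatrix& F, int n, const NumericVector& f) {
  const int m = F.ncol();
  int cnt = 0;
  for (int j = 0; j < n; ++j) {
    bool le = true, lt = false;
    for (int k = 0; k < m; ++k) {
      if (F(j, k) > f[k]) { le = false; break; }
      if (F(j, k) < f[k]) lt = true;
    }
    if (le && lt) ++cnt;
  }
  return cnt;
}
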